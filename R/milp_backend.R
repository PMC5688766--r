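# Mixed-integer programming backend. Problems are assembled in R as
# sparse matrices and solved in a batch by a bundled Python helper
# running scipy.optimize.milp (the HiGHS solver), so that one
# interpreter launch can serve hundreds of small instances.

MILP_BIG <- 1e30

milp_problem <- function(c, lb, ub, integrality,
                         ai = integer(), aj = integer(), ax = numeric(),
                         rlb = numeric(), rub = numeric(),
                         n_rows = 0L, time_limit = NULL) {
  list(n_vars = length(c), c = c, lb = lb, ub = ub,
       integrality = as.integer(integrality),
       n_rows = as.integer(n_rows), ai = ai, aj = aj, ax = ax,
       rlb = rlb, rub = rub, time_limit = time_limit)
}

python_binary <- function() {
  bin <- getOption("karyograph.python", Sys.getenv("KARYOGRAPH_PYTHON", "python"))
  path <- Sys.which(bin)
  if (!nzchar(path))
    stop("python interpreter '", bin, "' not found on PATH; the MIP ",
         "backend requires Python with scipy >= 1.9 ",
         "(set options(karyograph.python=) to point elsewhere)")
  path
}

#' Solve a batch of mixed-integer linear programs
#'
#' Internal entry point to the HiGHS backend (via
#' `scipy.optimize.milp`). Each problem is a list with fields `n_vars`,
#' `c`, `lb`, `ub`, `integrality`, sparse rows `ai`/`aj`/`ax` with
#' bounds `rlb`/`rub`, and `n_rows`. Solved to zero optimality gap.
#'
#' @param problems list of problems as built by the formulation layer.
#' @return list of results: `success`, `status`, `objective`, `x`.
#' @keywords internal
milp_solve_batch <- function(problems) {
  if (!length(problems)) return(list())
  script <- system.file("python", "milp_solve.py", package = "karyograph",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(list(problems = problems), fin,
                       auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(python_binary(), c(shQuote(script), shQuote(fin),
                                       shQuote(fout)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0L)
    stop("MIP backend failed (exit ", code, "):\n",
         paste(status, collapse = "\n"))
  out <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  out$results
}
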