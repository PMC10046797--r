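# HiGHS solver backend.
#
# The MILP is solved by HiGHS through scipy's `milp` interface, driven as a
# batch subprocess: all models of one call are serialised to JSON, solved in
# a single interpreter, and read back. Locating the interpreter honours, in
# order, option `dioptra.python`, environment variable `DIOPTRA_PYTHON`,
# then `python3`/`python` on the PATH.

find_python <- function() {
  cand <- c(getOption("dioptra.python", ""),
            Sys.getenv("DIOPTRA_PYTHON", ""),
            Sys.which("python3"), Sys.which("python"))
  cand <- cand[nzchar(cand)]
  if (!length(cand)) {
    stop("no python interpreter found for the HiGHS backend; ",
         "set options(dioptra.python=...) or DIOPTRA_PYTHON", call. = FALSE)
  }
  cand[[1L]]
}

solver_script <- function() {
  path <- system.file("python", "milp_solver.py", package = "dioptra")
  if (!nzchar(path)) stop("bundled solver script not found", call. = FALSE)
  path
}

# JSON has no Inf; encode as a large sentinel the worker maps back.
encode_bounds <- function(x) {
  x[x == Inf] <- 1e30
  x[x == -Inf] <- -1e30
  x
}

# problems: list of builds from build_dioptra_problem().
# Returns a list of raw solver results (status/objective/x/mip_gap).
highs_solve_batch <- function(problems, config) {
  payload <- list(
    options = list(time_limit = config$time_limit_s,
                   mip_rel_gap = config$relative_gap_target),
    problems = lapply(unname(problems), function(p) {
      list(n = p$n, obj = p$obj,
           A_ub = p$A_ub, b_ub = p$b_ub,
           A_eq = p$A_eq, b_eq = p$b_eq,
           lb = encode_bounds(p$lb), ub = encode_bounds(p$ub),
           integrality = p$integrality)
    })
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(find_python(), c(solver_script(), fin, fout),
                    stdout = NULL, stderr = "")
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("HiGHS backend subprocess failed (exit ", status, ")",
         call. = FALSE)
  }
  jsonlite::fromJSON(fout, simplifyVector = FALSE)
}

# scipy milp status codes: 0 optimal, 1 iteration/time limit,
# 2 infeasible, 3 unbounded, 4 other
map_solver_status <- function(res) {
  has_x <- !is.null(res$x)
  if (identical(res$status, 0L) || identical(res$status, 0)) {
    "OPTIMAL"
  } else if (has_x) {
    "FEASIBLE"
  } else {
    "NO_SOLUTION"
  }
}
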