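# Internal helpers shared across modules.

# Signal a classed condition so callers can test on error class rather than
# message text. All package errors inherit from "coopfit_error".
cf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "coopfit_error")))
}

cf_assert <- function(ok, msg, class = "coopfit_input_error") {
  if (!isTRUE(ok)) cf_stop(msg, class)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  cf_assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
            "seed must be a single finite number")
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Write via a one-argument writer function, atomically: the writer targets a
# temporary sibling path which is renamed into place only on success, so a
# failing run never leaves a partial output behind.
write_atomically <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) cf_stop(
    paste0("could not move temporary file into place at ", path),
    "coopfit_io_error")
  ok <- TRUE
  invisible(path)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Concentration unit -> micromolar conversion factors.
.conc_unit_factors <- c(
  "M" = 1e6, "mM" = 1e3, "uM" = 1, "µM" = 1, "nM" = 1e-3, "pM" = 1e-6
)

convert_to_uM <- function(x, unit) {
  f <- .conc_unit_factors[unit]
  if (anyNA(f)) cf_stop(
    paste0("unknown concentration unit(s): ",
           paste(unique(unit[is.na(f)]), collapse = ", ")),
    "coopfit_unit_error")
  unname(x * f)
}
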