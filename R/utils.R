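#' @import methods
#' @importFrom stats rnbinom rlnorm rnorm cor ks.test sd setNames
#' @importFrom utils modifyList
#' @importFrom data.table data.table as.data.table setDT setnames := .N .SD
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "..keep", "S0", "S_LR", "barcode", "cell_type", "criterion",
  "detection_rate", "e_L", "e_R", "gene", "group", "group_by", "ligand",
  "loop_strength", "max_s", "mean_expr", "n_cells", "n_support", "pair_id",
  "receiver", "receptor", "sender", "subclass", "survival_class",
  "timepoint", "overall", "lib", "value", "crit1", "crit2", "keep",
  "det_l", "det_r", "gmax", "idx", "n", "share_cond", "share_sham",
  "adjusted_share", "est_subclass_survival", "condition"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(fmt, ..., class = "lrcomm_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

abort_validation <- function(fmt, ...) {
  abort(fmt, ..., class = "lrcomm_validation_error")
}

check_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    abort_validation("'%s' must be a single number in [%s, %s], got %s",
                     name, format(lo), format(hi),
                     paste(format(x), collapse = ","))
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    abort_validation("'%s' must be TRUE or FALSE", name)
  invisible(x)
}

#' Deterministic child seed
#'
#' Derives a reproducible 31-bit seed for a named sub-stream from a master
#' seed, so independent stages never share an RNG stream.
#' @param seed master seed (integer).
#' @param key character tag of the sub-stream.
#' @return an integer seed in `[0, 2^31)`.
#' @keywords internal
child_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
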