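# Columns of a cohort data frame that are not assessment items.
RESERVED_COLUMNS <- c("person_id", "cohort", "age", "prior_use", "outcome", "split")

#' Item columns of a cohort data frame
#'
#' Every column of a cohort table that is not one of the reserved bookkeeping
#' columns (`person_id`, `cohort`, `age`, `prior_use`, `outcome`, `split`) is
#' treated as a dichotomous assessment item.
#'
#' @param dataset A cohort data frame.
#' @return Character vector of item column names.
#' @export
item_columns <- function(dataset) {
  setdiff(names(dataset), RESERVED_COLUMNS)
}

# Deterministic per-stage child seed from one master seed, so that e.g. the
# derivation/validation split and the outcome draw use independent streams
# while the whole run remains reproducible from a single integer.
child_seed <- function(seed, stage) {
  s <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(stage)) {
    s <- (s * 48271 + k) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary01 <- function(x) {
  !anyNA(x) && all(x == 0L | x == 1L)
}
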