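# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the caller's RNG state, so seeded package functions never perturb
#' user-level random streams. A `NULL` seed evaluates `code` unmodified.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Genus part of a taxon name: species-call names are "Genus_species"
# ("Lactobacillus_iners"); bare genus names pass through unchanged.
genus_of <- function(taxa) sub("_.*$", "", taxa)

# Stable order by decreasing value with ties broken by name ascending.
order_by_abundance <- function(values, names) {
  order(-values, names, method = "radix")
}

stop_if_not_scalar_count <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a single positive integer", what), call. = FALSE)
  invisible(x)
}
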