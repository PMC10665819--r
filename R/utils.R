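# Internal helpers shared across modules.

# Derive an independent 32-bit sub-seed from a user seed and a stream label,
# so that e.g. redrawing the gene p-values never perturbs the model topology.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 1009 + h * 97) %% .Machine$integer.max)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Count carbon atoms in a molecular formula
#'
#' Parses a Hill-style formula string (e.g. `"C6H12O6"`) into element counts
#' and returns the carbon count. Two-letter element symbols (`Cl`, `Ca`, ...)
#' are recognised so that chlorine is never mistaken for carbon.
#'
#' @param formula Character vector of molecular formulas.
#' @return Integer vector of carbon counts (0 for carbon-free species).
#' @examples
#' carbon_count(c("C6H12O6", "H2O", "CaCl2"))
#' @export
carbon_count <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(0L)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    n <- 0L
    for (tok in toks) {
      elem <- gsub("[0-9]", "", tok)
      cnt <- gsub("[^0-9]", "", tok)
      if (elem == "C") n <- n + if (nzchar(cnt)) as.integer(cnt) else 1L
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}

#' Canonical unordered pair key
#'
#' Metabolite pairs and ratios are identified by the string `"a~b"` with the
#' two ids in lexicographic order, so a pair compares equal regardless of
#' which member is named first. Vectorized.
#'
#' @param a,b Character vectors of ids.
#' @return Character vector of canonical keys.
#' @export
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "~"), paste(b, a, sep = "~"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
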