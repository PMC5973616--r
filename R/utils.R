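#' Reserved placeholder tokens
#'
#' The pipeline replaces entity mentions and numerals with reserved
#' placeholder tokens: the focal spice mention becomes `spice`, the focal
#' disease mention becomes `disease`, every non-focal entity mention becomes
#' `masked`, and numeric tokens become `number`. Defaults are uppercase so
#' they are disjoint from the lowercased text vocabulary.
#'
#' @param spice,disease,masked,number Single replacement strings.
#' @return Named character vector with elements `spice`, `disease`,
#'   `masked`, `number`.
#' @examples
#' reserved_tokens()
#' @export
reserved_tokens <- function(spice = "SPICE", disease = "DISEASE",
                            masked = "MASKED", number = "NUM") {
  out <- c(spice = spice, disease = disease, masked = masked, number = number)
  if (anyDuplicated(out) > 0) {
    abort("reserved tokens must be pairwise distinct")
  }
  out
}

# Deterministic pseudo-word factory. Consonant-vowel syllables keep the
# generated vocabulary disjoint from the English template banks.
new_word_factory <- function(blocked = character()) {
  syllables <- as.vector(outer(
    c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z"),
    c("a", "e", "i", "o", "u"), paste0
  ))
  used <- new.env(parent = emptyenv())
  for (w in blocked) assign(w, TRUE, envir = used)
  function(n_syllables = 3L) {
    repeat {
      w <- paste(sample(syllables, n_syllables, replace = TRUE), collapse = "")
      if (!exists(w, envir = used, inherits = FALSE)) {
        assign(w, TRUE, envir = used)
        return(w)
      }
    }
  }
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= 1, got %s",
                  name, deparse(x)))
  }
  as.integer(x)
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || any(x < 1) ||
      x[1] > x[2] || any(x != as.integer(x))) {
    abort(sprintf("`%s` must be an integer range c(lo, hi) with 1 <= lo <= hi",
                  name))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  as.numeric(x)
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}
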