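#' Growth-layer labels, ordinals and the continuous layer coordinate
#'
#' Tooth cementum accretes one growth layer group (GLG) per year: a wide
#' "light" layer deposited during the fast-growth season followed by a
#' narrower "dark" layer. The first five GLGs are labelled
#' `L1, D1, L2, D2, ..., L5, D5` (ordinals 1-10). The continuous layer
#' coordinate `ell` maps layer ordinal `k` to the half-open interval
#' `[k - 1, k)`, so `ell` runs over `[0, 10)` across the first five years of
#' life and "weaned by the end of year k" means ordinal `<= 2k`.
#'
#' @param label Character vector of layer labels (`"L1"`, `"D3"`, ...).
#' @param ordinal Integer vector of layer ordinals (1-10 for `L1`-`D5`;
#'   larger ordinals label later layers, e.g. 11 is `L6`).
#' @param ell Numeric vector of continuous layer coordinates in `[0, 10)`.
#'
#' @return `layer_ordinal()` returns an integer vector; `layer_label()` and
#'   `layer_of()` return character vectors; `layer_year()` returns the year
#'   of life (1-5) a layer belongs to.
#'
#' @examples
#' layer_ordinal(c("L1", "D2", "D5"))
#' layer_label(1:10)
#' layer_of(c(0, 3.2, 9.999))
#' @name layer-coordinate
NULL

glg_labels <- function() {
  paste0(rep(c("L", "D"), 5), rep(1:5, each = 2))
}

#' @rdname layer-coordinate
#' @export
layer_ordinal <- function(label) {
  ok <- is.na(label) | grepl("^[LD][0-9]+$", label)
  if (!all(ok)) {
    abort(sprintf(
      "Invalid layer label(s): %s. Labels look like 'L1', 'D2', ...",
      paste(unique(label[!ok]), collapse = ", ")
    ))
  }
  year <- as.integer(sub("^[LD]", "", label))
  dark <- substr(label, 1, 1) == "D"
  as.integer(2L * year - 1L + dark)
}

#' @rdname layer-coordinate
#' @export
layer_label <- function(ordinal) {
  if (any(!is.na(ordinal) & (ordinal < 1 | ordinal != floor(ordinal)))) {
    abort("Layer ordinals must be positive integers.")
  }
  year <- (as.integer(ordinal) + 1L) %/% 2L
  side <- ifelse(as.integer(ordinal) %% 2L == 1L, "L", "D")
  out <- paste0(side, year)
  out[is.na(ordinal)] <- NA_character_
  out
}

#' @rdname layer-coordinate
#' @export
layer_of <- function(ell) {
  bad <- !is.na(ell) & (ell < 0 | ell >= 10)
  if (any(bad)) {
    abort(sprintf(
      "Layer coordinate out of range [0, 10): %s",
      paste(format(utils::head(ell[bad], 3)), collapse = ", ")
    ))
  }
  layer_label(floor(ell) + 1)
}

#' @rdname layer-coordinate
#' @export
layer_year <- function(ordinal) {
  as.integer(ceiling(ordinal / 2))
}
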