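# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
lk_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "lipidkin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @keywords internal
#' @noRd
lk_assert <- function(cond, msg, class = "lipidkin_invalid_input") {
  if (!isTRUE(cond)) lk_error(msg, class)
  invisible(TRUE)
}

# Minimum-image displacement for orthorhombic boxes: works elementwise and
# recycles `box` against `d` (both may be vectors/matrices of matching shape).
#' @keywords internal
#' @noRd
min_image <- function(d, box) {
  d - box * round(d / box)
}

#' @keywords internal
#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

# Standard amino-acid residue names (three-letter), shared by atomistic and
# MARTINI naming; used to classify particles as protein.
AA_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "HIE", "HID", "HIP"
)
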