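#' Particle metadata table
#'
#' A `ParticleMeta` is a data frame with one row per particle (bead or atom)
#' describing identity and classification. It is the vocabulary every analysis
#' consumes: selections, lipid species, and residue bookkeeping all resolve
#' against it.
#'
#' @param particle_index 0-based integer indices, unique and contiguous from 0.
#' @param residue_id Integer residue identifiers (author numbering preserved).
#' @param residue_name Character residue names (e.g. `"ALA"`, `"POPC"`).
#' @param segment_id Character segment/chain identifiers.
#' @param particle_name Character bead or atom names (e.g. `"BB"`, `"CA"`).
#' @param category One of `"protein"`, `"lipid"`, `"other"` per particle.
#' @param species Lipid species label (e.g. `"GM3"`, `"PIP2"`); empty string
#'   for non-lipids.
#'
#' @return A `data.frame` of class `ParticleMeta`.
#' @export
particle_meta <- function(particle_index, residue_id, residue_name, segment_id,
                          particle_name, category, species) {
  n <- length(particle_index)
  lk_assert(n >= 1L, "ParticleMeta needs at least one particle")
  lk_assert(
    identical(as.integer(particle_index), seq_len(n) - 1L),
    "particle_index must be unique and contiguous from 0"
  )
  lk_assert(all(category %in% c("protein", "lipid", "other")),
            "category must be one of protein/lipid/other")
  lk_assert(all(nzchar(species[category == "lipid"])),
            "lipid particles must carry a non-empty species label")
  meta <- data.frame(
    particle_index = as.integer(particle_index),
    residue_id = as.integer(residue_id),
    residue_name = as.character(residue_name),
    segment_id = as.character(segment_id),
    particle_name = as.character(particle_name),
    category = as.character(category),
    species = as.character(species),
    stringsAsFactors = FALSE
  )
  class(meta) <- c("ParticleMeta", "data.frame")
  meta
}

#' Number of particles described by a ParticleMeta
#' @param meta A [particle_meta()] table.
#' @return Integer particle count.
#' @export
n_particles <- function(meta) nrow(meta)

# Molecule key: a (segment_id, residue_id) pair identifies one molecule-residue.
#' @keywords internal
#' @noRd
molecule_key <- function(meta) {
  paste(meta$segment_id, meta$residue_id, sep = "/")
}

#' Resolve a selection expression to particle indices
#'
#' The selection mini-language combines clauses with `and` / `or`
#' (`and` binds tighter). Clauses:
#' \itemize{
#'   \item `residue_id A-B` or `residue_id A` (ranges inclusive of both ends)
#'   \item `residue_name NAME` / `particle_name NAME`
#'   \item `particle_name in (N1 N2 ...)` (also for residue_name/species)
#'   \item `category protein|lipid|other`
#'   \item `species LABEL`
#'   \item `not <clause>`
#' }
#'
#' @param meta A [particle_meta()] table.
#' @param expression Selection string, e.g.
#'   `"residue_id 27-132 and category protein"`.
#' @return Sorted integer vector of 0-based particle indices.
#' @export
#' @examples
#' meta <- particle_meta(0:1, c(1L, 2L), c("ALA", "POPC"), c("A", "M"),
#'                       c("CA", "PO4"), c("protein", "lipid"), c("", "POPC"))
#' resolve_selection(meta, "category protein")
resolve_selection <- function(meta, expression) {
  lk_assert(is.character(expression) && length(expression) == 1L &&
              nzchar(trimws(expression)), "selection expression must be a string")
  mask <- parse_or(meta, trimws(expression))
  idx <- meta$particle_index[mask]
  if (length(idx) == 0L) {
    lk_error(sprintf("selection '%s' matched no particles", expression),
             "lipidkin_empty_selection")
  }
  sort(idx)
}

# --- selection parser -------------------------------------------------------
# grammar:  or_expr  := and_expr ( "or" and_expr )*
#           and_expr := clause ( "and" clause )*
# split at top level only (the sole nesting construct is "in ( ... )").

#' @keywords internal
#' @noRd
split_toplevel <- function(text, word) {
  toks <- strsplit(text, "\\s+")[[1]]
  depth <- 0L
  parts <- character(0)
  cur <- character(0)
  for (tok in toks) {
    depth <- depth + lengths(regmatches(tok, gregexpr("\\(", tok)))
    if (depth == 0L && identical(tolower(tok), word)) {
      parts <- c(parts, paste(cur, collapse = " "))
      cur <- character(0)
    } else {
      cur <- c(cur, tok)
    }
    depth <- depth - lengths(regmatches(tok, gregexpr("\\)", tok)))
  }
  c(parts, paste(cur, collapse = " "))
}

#' @keywords internal
#' @noRd
parse_or <- function(meta, text) {
  parts <- split_toplevel(text, "or")
  Reduce(`|`, lapply(parts, function(p) parse_and(meta, p)))
}

#' @keywords internal
#' @noRd
parse_and <- function(meta, text) {
  parts <- split_toplevel(text, "and")
  Reduce(`&`, lapply(parts, function(p) parse_clause(meta, p)))
}

#' @keywords internal
#' @noRd
parse_clause <- function(meta, text) {
  text <- trimws(text)
  if (grepl("^not\\s+", text, ignore.case = TRUE)) {
    return(!parse_clause(meta, sub("^not\\s+", "", text, ignore.case = TRUE)))
  }
  m <- regmatches(text, regexec(
    "^(residue_id|residue_name|particle_name|category|species)\\s+(.+)$", text))[[1]]
  if (length(m) == 0L) {
    lk_error(sprintf("cannot parse selection clause '%s'", text),
             "lipidkin_selection_syntax")
  }
  field <- m[2]
  value <- trimws(m[3])
  if (field == "residue_id") {
    rng <- regmatches(value, regexec("^(-?\\d+)\\s*-\\s*(-?\\d+)$", value))[[1]]
    if (length(rng) == 3L) {
      lo <- as.integer(rng[2]); hi <- as.integer(rng[3])
    } else {
      lk_assert(grepl("^-?\\d+$", value),
                sprintf("bad residue_id clause '%s'", value),
                "lipidkin_selection_syntax")
      lo <- hi <- as.integer(value)
    }
    return(meta$residue_id >= lo & meta$residue_id <= hi)
  }
  vals <- if (grepl("^in\\s*\\(", value)) {
    inner <- sub("^in\\s*\\(", "", value)
    inner <- sub("\\)\\s*$", "", inner)
    strsplit(trimws(inner), "[[:space:],]+")[[1]]
  } else {
    value
  }
  meta[[field]] %in% vals
}
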