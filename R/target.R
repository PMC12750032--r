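# Target records: the stoichiometry container describing a full complex
# (polymer entities with copy counts plus non-polymer entities), as found in
# a pre-release entry, and their JSON serialization.

#' Polymer entity of a target
#'
#' @param entity_id identifier within the target.
#' @param noncanonical_seq character vector of component IDs.
#' @param copy_count number of chains of this entity in the complex.
#' @param parent_map component dictionary table, see [component_parents()].
#' @return list of class `polymer_entity` with the derived `canonical_seq`,
#'   `kind`, and validity flag; invalid entities carry a `reason`.
#' @export
polymer_entity <- function(entity_id, noncanonical_seq, copy_count = 1L,
                           parent_map = component_parents()) {
  stopifnot(is_string(entity_id), copy_count >= 1)
  can <- derive_canonical(noncanonical_seq, parent_map)
  kind <- NA_character_
  if (can$valid) {
    idx <- match(noncanonical_seq, parent_map$component_id)
    cls <- unique(parent_map$class[idx])
    alph <- if (all(cls == "amino")) "amino"
            else if (all(cls == "nucleic-dna")) "nucleic-dna"
            else if (all(cls == "nucleic-rna")) "nucleic-rna"
            else NA_character_
    if (is.na(alph)) {
      can$valid <- FALSE
      can$reason <- "alphabet cannot be unambiguously assigned"
    } else kind <- classify_entity_kind(can$canonical, alph)
  }
  structure(list(entity_id = entity_id, noncanonical_seq = noncanonical_seq,
                 canonical_seq = can$canonical, kind = kind,
                 copy_count = as.integer(copy_count), valid = can$valid,
                 reason = can$reason),
            class = "polymer_entity")
}

#' Non-polymer (ligand) entity of a target
#'
#' @param entity_id identifier within the target.
#' @param component_id chemical component ID.
#' @param smiles SMILES string of the component.
#' @param copy_count number of copies in the complex.
#' @return list of class `nonpolymer_entity`; `heavy_atom_count` is derived
#'   from the SMILES.
#' @export
nonpolymer_entity <- function(entity_id, component_id, smiles, copy_count = 1L) {
  stopifnot(is_string(entity_id), is_string(component_id), is_string(smiles),
            copy_count >= 1)
  g <- ligand_graph(smiles)
  structure(list(entity_id = entity_id, component_id = component_id,
                 smiles = smiles, copy_count = as.integer(copy_count),
                 heavy_atom_count = length(g$elements)),
            class = "nonpolymer_entity")
}

#' Target complex record
#'
#' The full stoichiometry of one modelling target: all polymer entities with
#' copy counts plus all non-polymer (ligand) entities.
#'
#' @param target_id identifier.
#' @param polymers list of [polymer_entity()] (at least one).
#' @param nonpolymers list of [nonpolymer_entity()].
#' @return list of class `target_complex`.
#' @export
target_complex <- function(target_id, polymers, nonpolymers = list()) {
  stopifnot(is_string(target_id), length(polymers) >= 1)
  structure(list(target_id = target_id, polymers = polymers,
                 nonpolymers = nonpolymers),
            class = "target_complex")
}

#' @export
print.target_complex <- function(x, ...) {
  cat("<target_complex> ", x$target_id, "\n", sep = "")
  for (p in x$polymers)
    cat(sprintf("  %s %s x%d (%d res)%s\n", p$entity_id,
                ifelse(is.na(p$kind), "invalid", p$kind), p$copy_count,
                length(p$noncanonical_seq),
                if (!p$valid) paste0(" [", p$reason, "]") else ""))
  for (np in x$nonpolymers)
    cat(sprintf("  %s ligand %s x%d (%d heavy atoms)\n", np$entity_id,
                np$component_id, np$copy_count, np$heavy_atom_count))
  invisible(x)
}

#' Is a target admissible for benchmarking?
#'
#' A target is excluded when any polymer entity is invalid: modified
#' residues without a dictionary parent, unknown or non-linking residues,
#' mixed amino/nucleic sequences, or an ambiguous alphabet.
#'
#' @param target a [target_complex()].
#' @return list with `admissible` and `reason`.
#' @export
target_admissible <- function(target) {
  for (p in target$polymers)
    if (!p$valid)
      return(list(admissible = FALSE,
                  reason = paste0(p$entity_id, ": ", p$reason)))
  list(admissible = TRUE, reason = "")
}

#' Write / read target records as JSON
#'
#' The record schema is a JSON object per target: `target_id`, `polymers`
#' (entity_id, components, copy_count) and `nonpolymers` (entity_id,
#' component_id, smiles, copy_count).
#'
#' @param targets list of [target_complex()].
#' @param path output path.
#' @return `path` invisibly for the writer; a list of targets for the reader.
#' @export
write_targets_json <- function(targets, path) {
  recs <- lapply(targets, function(t) list(
    target_id = t$target_id,
    polymers = lapply(t$polymers, function(p) list(
      entity_id = p$entity_id, components = p$noncanonical_seq,
      copy_count = p$copy_count)),
    nonpolymers = lapply(t$nonpolymers, function(np) list(
      entity_id = np$entity_id, component_id = np$component_id,
      smiles = np$smiles, copy_count = np$copy_count))))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_targets_json
#' @export
read_targets_json <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    target_complex(
      r$target_id,
      polymers = lapply(r$polymers, function(p)
        polymer_entity(p$entity_id, unlist(p$components), p$copy_count)),
      nonpolymers = lapply(r$nonpolymers, function(np)
        nonpolymer_entity(np$entity_id, np$component_id, np$smiles,
                          np$copy_count)))
  })
}
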