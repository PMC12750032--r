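# Assembly selection, score aggregation and per-target reporting.

#' Weighted mean of ligand interface scores
#'
#' Aggregates per-ligand LDDT-PLI values with the number of heavy atoms as
#' weight, so that single-atom ions cannot dominate the average.
#'
#' @param per_ligand list of pose-score records (fields `lddt_pli`,
#'   `heavy_atoms`), see [score_complex()].
#' @return weighted mean, or `NA` when no score is defined.
#' @export
weighted_pli <- function(per_ligand) {
  s <- vapply(per_ligand, function(p) p$lddt_pli %||% NA_real_, 1)
  w <- vapply(per_ligand, function(p) as.numeric(p$heavy_atoms), 1)
  ok <- !is.na(s)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] * s[ok]) / sum(w[ok])
}

#' Fraction of successfully predicted ligand poses
#'
#' A pose is successful when its BiSyRMSD is strictly below the threshold;
#' the count of successes is divided by the total number of reference
#' ligands, so unpredicted copies count as failures.
#'
#' @param per_ligand list of pose-score records (field `bisy_rmsd`, `NA`
#'   for unscored ligands).
#' @param n_reference_ligands total ligands in the target (>= 1).
#' @param threshold success cutoff in Angstrom.
#' @return fraction in [0,1]; `NA` when the target has no ligand.
#' @export
success_fraction <- function(per_ligand, n_reference_ligands, threshold = 2.0) {
  if (n_reference_ligands < 1) return(NA_real_)
  r <- vapply(per_ligand, function(p) p$bisy_rmsd %||% NA_real_, 1)
  sum(!is.na(r) & r < threshold) / n_reference_ligands
}

#' Best-scored pose per ligand entity
#'
#' Keeps, for every ligand entity, the copy with the lowest BiSyRMSD (ties
#' resolved by the higher LDDT-PLI), so multiple-copy prediction is not
#' penalised. Entities with no scored copy are absent from the result.
#'
#' @param per_ligand list of pose-score records.
#' @param entity_of named character vector: reference ligand ID -> entity ID.
#' @return list of pose-score records, one per entity with a scored copy.
#' @export
best_pose_per_entity <- function(per_ligand, entity_of) {
  scored <- Filter(function(p) !is.na(p$bisy_rmsd %||% NA_real_), per_ligand)
  if (!length(scored)) return(list())
  ent <- vapply(scored, function(p) entity_of[[p$ligand_ref]], "")
  out <- lapply(split(scored, ent), function(grp) {
    r <- vapply(grp, function(p) p$bisy_rmsd, 1)
    s <- vapply(grp, function(p) p$lddt_pli %||% -Inf, 1)
    grp[[order(r, -s)[1]]]
  })
  out[order(names(out))]
}

#' Select the reported assembly among candidates
#'
#' Models are scored against every biological assembly; polymer scores are
#' reported against the assembly with the highest LDDT, ligand scores
#' against the assembly scoring the most ligands, with ties broken by the
#' higher sum of LDDT-PLI, then the lower sum of BiSyRMSD, then the lowest
#' assembly ID.
#'
#' @param per_assembly named list (by assembly ID) of per-assembly results
#'   with fields `lddt`, `n_ligands_scored`, `sum_pli`, `sum_bisy`.
#' @return list of class `assembly_choice` with `polymer_assembly`,
#'   `ligand_assembly` and `rationale`.
#' @export
select_assembly <- function(per_assembly) {
  stopifnot(length(per_assembly) >= 1)
  ids <- names(per_assembly)
  if (length(ids) == 1)
    return(structure(list(polymer_assembly = ids, ligand_assembly = ids,
                          rationale = "only assembly"),
                     class = "assembly_choice"))
  l <- vapply(per_assembly, function(a) a$lddt %||% NA_real_, 1)
  l[is.na(l)] <- -Inf
  poly <- ids[order(-l, ids)][1]
  nl <- vapply(per_assembly, function(a) a$n_ligands_scored %||% 0L, 1L)
  sp <- vapply(per_assembly, function(a) a$sum_pli %||% 0, 1)
  sb <- vapply(per_assembly, function(a) a$sum_bisy %||% Inf, 1)
  lig <- ids[order(-nl, -sp, sb, ids)][1]
  structure(list(polymer_assembly = poly, ligand_assembly = lig,
                 rationale = sprintf(
                   "polymer: highest LDDT (%s); ligand: most ligands scored, then sum LDDT-PLI desc, sum BiSyRMSD asc (%s)",
                   poly, lig)),
            class = "assembly_choice")
}

#' Recompute polymer scores on mapped chains only
#'
#' Restricts the reference to the chains that received a model partner and
#' recomputes LDDT and interface LDDT on the substructure, removing the
#' missing-chain penalty. The mapped interface LDDT is undefined when the
#' mapped substructure has no inter-chain contact (e.g. a single mapped
#' chain).
#'
#' @param model,reference [eval_structure()] objects.
#' @param mapping the `chain_mapping` from the initial full-complex scoring.
#' @param params [lddt_params()].
#' @return list with `mapped_lddt` and `mapped_ilddt` (either may be `NA`).
#' @export
mapped_scores <- function(model, reference, mapping, params = lddt_params()) {
  if (!nrow(mapping$pairs))
    return(list(mapped_lddt = NA_real_, mapped_ilddt = NA_real_))
  keep_ref <- drop_chains(reference,
                          setdiff(reference$chains$chain_id,
                                  c(mapping$pairs$reference,
                                    ligand_chain_ids(reference))))
  sub_map <- new_chain_mapping(mapping$pairs, mapping$pairs$model,
                               mapping$pairs$reference)
  list(mapped_lddt = lddt(model, keep_ref, sub_map, params)$score,
       mapped_ilddt = ilddt(model, keep_ref, sub_map, params)$score)
}

## ------------------------------------------------------------------------
## Full per-target scoring

# Ligand graph for a structure's ligand chain: from the target record SMILES
# when available, otherwise bonds are inferred from interatomic distances.
structure_ligand_graph <- function(s, chain_id, target = NULL) {
  a <- chain_atoms(s, chain_id, heavy_only = TRUE)
  if (!is.null(target)) {
    for (np in target$nonpolymers)
      if (np$component_id == a$comp_id[1]) {
        g <- ligand_graph(np$smiles)
        if (length(g$elements) == nrow(a)) return(g)
      }
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  bonds <- matrix(integer(), ncol = 2)
  if (nrow(a) > 1) {
    d <- as.matrix(stats::dist(xyz))
    ut <- which(upper.tri(d) & d < 1.9, arr.ind = TRUE)
    bonds <- ut
  }
  structure(list(elements = toupper(a$element), bonds = bonds, smiles = ""),
            class = "ligand_graph")
}

#' Score a model complex against one or more reference assemblies
#'
#' Runs the full evaluation for a single model: chain mapping, LDDT,
#' interface LDDT, TM-score and per-ligand pose scores against every
#' candidate assembly, assembly selection, mapped-chain rescoring, weighted
#' ligand aggregation, pose success fractions at 1/2/5 Angstrom, and the
#' best-pose-per-entity variant.
#'
#' @param model an [eval_structure()].
#' @param assemblies named list of reference [eval_structure()] objects
#'   (one per biological assembly); a bare structure is treated as the only
#'   assembly.
#' @param target optional [target_complex()] providing ligand SMILES and
#'   entity copy counts.
#' @param params [lddt_params()].
#' @param site_radius binding-site radius for BiSyRMSD, Angstrom.
#' @param automorphism_cap cap on enumerated ligand automorphisms.
#' @param server_id,model_rank provenance fields carried into the report.
#' @return object of class `score_report`.
#' @export
score_complex <- function(model, assemblies, target = NULL,
                          params = lddt_params(), site_radius = 4.0,
                          automorphism_cap = 10000L,
                          server_id = "server", model_rank = 1L) {
  if (inherits(assemblies, "eval_structure"))
    assemblies <- stats::setNames(list(assemblies),
                                  assemblies[["assembly_id"]] %||% "1")
  if (is.null(names(assemblies)) || any(!nzchar(names(assemblies))))
    names(assemblies) <- as.character(seq_along(assemblies))

  per_assembly <- lapply(names(assemblies), function(aid) {
    reference <- assemblies[[aid]]
    cmap <- map_chains(model, reference)
    l <- lddt(model, reference, cmap, params)
    il <- ilddt(model, reference, cmap, params)
    tm <- tm_score(model, reference, cmap)
    mg <- lapply(stats::setNames(nm = ligand_chain_ids(model)),
                 function(cid) structure_ligand_graph(model, cid, target))
    rg <- lapply(stats::setNames(nm = ligand_chain_ids(reference)),
                 function(cid) structure_ligand_graph(reference, cid, target))
    autos <- lapply(rg, ligand_automorphisms, cap = automorphism_cap)
    pose_fn <- function(m, r) {
      s <- lddt_pli(model, reference, list(model = m, reference = r), cmap,
                    autos[[r]], params)$score
      if (is.na(s)) 0 else s
    }
    lmap <- map_ligands(mg, rg, pose_fn)
    per_ligand <- lapply(names(rg), function(r) {
      hit <- lmap$pairs$model[lmap$pairs$reference == r]
      if (!length(hit))
        return(list(ligand_ref = r, comp_id = ligand_comp(reference, r),
                    lddt_pli = NA_real_, bisy_rmsd = NA_real_,
                    heavy_atoms = length(rg[[r]]$elements),
                    reason = "no isomorphic model ligand"))
      pair <- list(model = hit[1], reference = r)
      pli <- lddt_pli(model, reference, pair, cmap, autos[[r]], params)
      bs <- bisy_rmsd(model, reference, pair, cmap, autos[[r]], site_radius)
      list(ligand_ref = r, comp_id = ligand_comp(reference, r),
           lddt_pli = pli$score, bisy_rmsd = bs$rmsd,
           heavy_atoms = length(rg[[r]]$elements),
           reason = paste(c(pli$reason, bs$reason)[nzchar(c(pli$reason,
                                                            bs$reason))],
                          collapse = "; "))
    })
    scored <- vapply(per_ligand, function(p) !is.na(p$bisy_rmsd), TRUE)
    list(lddt = l$score, ilddt = il$score, tm = tm$score, mapping = cmap,
         per_ligand = per_ligand, n_ligands_scored = sum(scored),
         sum_pli = sum(vapply(per_ligand, function(p)
           if (is.na(p$lddt_pli)) 0 else p$lddt_pli, 1)),
         sum_bisy = sum(vapply(per_ligand, function(p)
           if (is.na(p$bisy_rmsd)) 0 else p$bisy_rmsd, 1)))
  })
  names(per_assembly) <- names(assemblies)

  choice <- select_assembly(per_assembly)
  pa <- per_assembly[[choice$polymer_assembly]]
  la <- per_assembly[[choice$ligand_assembly]]
  ref_poly <- assemblies[[choice$polymer_assembly]]
  ms <- mapped_scores(model, ref_poly, pa$mapping, params)

  n_ref_lig <- length(la$per_ligand)
  entity_of <- ligand_entities(assemblies[[choice$ligand_assembly]], target)
  best_per_entity <- best_pose_per_entity(la$per_ligand, entity_of)
  n_entities <- length(unique(entity_of[vapply(la$per_ligand,
                                               function(p) p$ligand_ref, "")]))
  succ_ent <- function(th) {
    if (n_entities == 0) return(NA_real_)
    r <- vapply(best_per_entity, function(p) p$bisy_rmsd, 1)
    sum(r < th) / n_entities
  }

  structure(list(
    target_id = target$target_id %||% ref_poly$structure_id,
    server_id = server_id, model_rank = as.integer(model_rank),
    assembly_choice = choice,
    lddt = pa$lddt, mapped_lddt = ms$mapped_lddt,
    ilddt = pa$ilddt, mapped_ilddt = ms$mapped_ilddt,
    tm = pa$tm,
    lddt_pli_weighted = if (n_ref_lig) weighted_pli(la$per_ligand) else NA_real_,
    success_frac_1A = if (n_ref_lig) success_fraction(la$per_ligand, n_ref_lig, 1) else NA_real_,
    success_frac_2A = if (n_ref_lig) success_fraction(la$per_ligand, n_ref_lig, 2) else NA_real_,
    success_frac_5A = if (n_ref_lig) success_fraction(la$per_ligand, n_ref_lig, 5) else NA_real_,
    success_frac_entity_2A = if (n_ref_lig) succ_ent(2) else NA_real_,
    per_ligand = la$per_ligand,
    best_pose_per_entity = best_per_entity,
    chain_mapping = pa$mapping,
    oligo_state_predicted = length(polymer_chain_ids(model)),
    oligo_state_reference = length(polymer_chain_ids(ref_poly)),
    per_assembly = lapply(per_assembly, function(a)
      a[c("lddt", "ilddt", "tm", "n_ligands_scored", "sum_pli", "sum_bisy")])),
    class = "score_report")
}

ligand_comp <- function(s, chain_id) {
  s$atoms$comp_id[s$atoms$chain_id == chain_id][1]
}

# Reference ligand chain -> ligand entity ID. Uses the chain table's
# entity_ref when present, else the target record by component ID, else the
# component ID itself.
ligand_entities <- function(reference, target = NULL) {
  ids <- ligand_chain_ids(reference)
  ent <- reference$chains$entity_ref[match(ids, reference$chains$chain_id)]
  comp <- vapply(ids, function(cid) ligand_comp(reference, cid), "")
  if (!is.null(target)) {
    by_comp <- stats::setNames(
      vapply(target$nonpolymers, function(np) np$entity_id, ""),
      vapply(target$nonpolymers, function(np) np$component_id, ""))
    fill <- !nzchar(ent) & comp %in% names(by_comp)
    ent[fill] <- by_comp[comp[fill]]
  }
  ent[!nzchar(ent)] <- comp[!nzchar(ent)]
  stats::setNames(ent, ids)
}

#' @export
print.score_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.3f", v)
  cat("<score_report> ", x$target_id, " / ", x$server_id, " (model ",
      x$model_rank, ")\n", sep = "")
  cat("  LDDT ", fmt(x$lddt), "  mapped ", fmt(x$mapped_lddt),
      "  iLDDT ", fmt(x$ilddt), "  mapped ", fmt(x$mapped_ilddt),
      "  TM ", fmt(x$tm), "\n", sep = "")
  cat("  oligomeric state: predicted ", x$oligo_state_predicted,
      " / reference ", x$oligo_state_reference, "\n", sep = "")
  if (length(x$per_ligand)) {
    cat("  ligand LDDT-PLI (weighted) ", fmt(x$lddt_pli_weighted),
        "; success 1/2/5 A: ", fmt(x$success_frac_1A), " ",
        fmt(x$success_frac_2A), " ", fmt(x$success_frac_5A), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a score report to JSON
#'
#' Undefined scores are written as explicit nulls together with a reason
#' code; they are never conflated with zero.
#'
#' @param report a `score_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (is.data.frame(x)) x
  else unclass(x)
}

## ------------------------------------------------------------------------
## Server comparison

#' Common-subset comparison of servers
#'
#' Servers predict disjoint target sets, so averages over all targets are
#' not comparable. This restricts every selected server to the intersection
#' of their predicted target sets and summarises each score there.
#'
#' @param results named list: server -> data.frame with a `target_id`
#'   column and numeric score columns.
#' @param selected servers to compare (default: all).
#' @return list with `n` (common-subset size), `targets`, and `summary`
#'   (long data.frame: server, metric, mean, median, n_defined).
#' @export
common_subset <- function(results, selected = names(results)) {
  stopifnot(length(selected) >= 1, all(selected %in% names(results)))
  sets <- lapply(results[selected], function(d) unique(d$target_id))
  common <- Reduce(intersect, sets)
  metrics <- setdiff(names(results[[selected[1]]]), "target_id")
  rows <- list()
  for (srv in selected) {
    d <- results[[srv]]
    d <- d[d$target_id %in% common, , drop = FALSE]
    for (m in intersect(metrics, names(d))) {
      v <- d[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        server = srv, metric = m,
        mean = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
        median = if (any(!is.na(v))) stats::median(v, na.rm = TRUE) else NA_real_,
        n_defined = sum(!is.na(v)), stringsAsFactors = FALSE)
    }
  }
  list(n = length(common), targets = sort(common),
       summary = if (length(rows)) do.call(rbind, rows) else
         data.frame(server = character(), metric = character(),
                    mean = numeric(), median = numeric(),
                    n_defined = integer()))
}
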