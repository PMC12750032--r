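# Chain and ligand mapping: injective assignment of model components onto
# reference components, and ligand graph symmetry handling.

#' Ligand connectivity graph from SMILES
#'
#' Heavy-atom graph of a chemical component: element labels and bonds, with
#' bond orders deliberately ignored (aromatic/kekule dialects then agree).
#'
#' @param smiles SMILES string.
#' @return list of class `ligand_graph` with `elements` (character vector in
#'   atom order), `bonds` (2-column matrix of atom indices), and the source
#'   `smiles`.
#' @export
ligand_graph <- function(smiles) {
  stopifnot(is_string(smiles))
  # single-atom shortcut also covers bare ions such as [ZN+2]
  m <- regmatches(smiles,
                  regexec("^\\[([A-Za-z][A-Za-z]?)[+-]?[0-9]*[+-]?\\]$",
                          smiles))[[1]]
  if (length(m) == 2) {
    el <- toupper(m[2])
    if (!valid_element(el)) stop("unparseable SMILES: ", smiles)
    return(structure(list(elements = el,
                          bonds = matrix(integer(), ncol = 2), smiles = smiles),
                     class = "ligand_graph"))
  }
  if (smiles == "O")
    return(structure(list(elements = "O", bonds = matrix(integer(), ncol = 2),
                          smiles = smiles), class = "ligand_graph"))
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) stop("unparseable SMILES: ", smiles))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  el <- toupper(gsub("_.*$", "", rownames(ab)))
  heavy <- which(el != "H")
  relab <- match(seq_along(el), heavy)
  bonds <- matrix(integer(), ncol = 2)
  if (length(bb) && nrow(bb))
    bonds <- cbind(relab[bb[, 1]], relab[bb[, 2]])
  bonds <- bonds[stats::complete.cases(bonds), , drop = FALSE]
  structure(list(elements = el[heavy], bonds = bonds, smiles = smiles),
            class = "ligand_graph")
}

lig_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$elements), directed = FALSE)
  if (nrow(g$bonds)) ig <- igraph::add_edges(ig, t(g$bonds))
  ig
}

element_colors <- function(g, vocab = NULL) {
  vocab <- vocab %||% sort(unique(g$elements))
  match(g$elements, vocab)
}

#' Enumerate ligand graph automorphisms
#'
#' All element- and bond-preserving atom permutations of a ligand graph,
#' used for symmetry correction of pose RMSDs. Enumeration is VF2-based;
#' the list always contains the identity and is truncated at `cap` with a
#' warning flag.
#'
#' @param graph a [ligand_graph()].
#' @param cap maximum number of permutations returned.
#' @return list of integer permutation vectors (`perm[i]` = reference atom
#'   matched to atom `i`), with attribute `truncated`.
#' @export
ligand_automorphisms <- function(graph, cap = 10000L) {
  n <- length(graph$elements)
  if (n == 0) stop("empty ligand graph")
  ig <- lig_igraph(graph)
  if (n > 1 && igraph::components(ig)$no > 1)
    stop("disconnected ligand graph")
  cols <- element_colors(graph)
  maps <- igraph::isomorphisms(ig, ig, method = "vf2",
                               vertex.color1 = cols, vertex.color2 = cols)
  perms <- lapply(maps, as.integer)
  # deterministic order: identity first, then lexicographic
  ord <- order(vapply(perms, function(p) paste(sprintf("%04d", p), collapse = ""),
                      ""))
  perms <- perms[ord]
  truncated <- FALSE
  if (length(perms) > cap) {
    perms <- perms[seq_len(cap)]
    truncated <- TRUE
  }
  attr(perms, "truncated") <- truncated
  perms
}

graphs_isomorphic <- function(g1, g2) {
  if (length(g1$elements) != length(g2$elements)) return(FALSE)
  if (nrow(g1$bonds) != nrow(g2$bonds)) return(FALSE)
  vocab <- sort(unique(c(g1$elements, g2$elements)))
  igraph::is_isomorphic_to(lig_igraph(g1), lig_igraph(g2), method = "vf2",
                           vertex.color1 = element_colors(g1, vocab),
                           vertex.color2 = element_colors(g2, vocab))
}

## ------------------------------------------------------------------------
## Chain mapping

# Entity-compatibility of a model and a reference polymer chain: identical
# entity_ref when both are annotated, otherwise identical derived sequence.
chains_compatible <- function(model, reference, mc, rc) {
  me <- model$chains$entity_ref[model$chains$chain_id == mc]
  re <- reference$chains$entity_ref[reference$chains$chain_id == rc]
  mk <- model$chains$kind[model$chains$chain_id == mc]
  rk <- reference$chains$kind[reference$chains$chain_id == rc]
  if (mk != rk) return(FALSE)
  if (nzchar(me) && nzchar(re)) return(me == re)
  isTRUE(tryCatch(chain_sequence(model, mc) == chain_sequence(reference, rc),
                  error = function(e) FALSE))
}

#' Map model chains onto reference chains
#'
#' Finds an injective assignment of model polymer chains to
#' entity-compatible reference polymer chains maximising a complex-context
#' score (backbone LDDT by default). Assignments are enumerated exhaustively
#' while the combinatorial size stays small (up to 6 interchangeable copies
#' per entity); beyond that a greedy seed refined by pairwise swaps is used.
#' Reference chains without a partner are reported unmapped and incur the
#' stoichiometry penalty downstream. Ties between equally scoring
#' assignments are broken by lexicographic (model, reference) pair order.
#'
#' @param model,reference [eval_structure()] objects.
#' @param score_fn function(mapping) -> total score; defaults to backbone
#'   LDDT of the model under the candidate mapping.
#' @param exhaustive_limit maximum number of complete assignments to
#'   enumerate exhaustively.
#' @return object of class `chain_mapping`: list with `pairs` (data.frame
#'   model, reference), `unmapped_model`, `unmapped_reference`.
#' @export
map_chains <- function(model, reference, score_fn = NULL,
                       exhaustive_limit = 720L) {
  mch <- polymer_chain_ids(model)
  rch <- polymer_chain_ids(reference)
  compat <- matrix(FALSE, length(mch), length(rch),
                   dimnames = list(mch, rch))
  for (i in seq_along(mch)) for (j in seq_along(rch))
    compat[i, j] <- chains_compatible(model, reference, mch[i], rch[j])
  if (is.null(score_fn))
    score_fn <- function(mapping)
      lddt(model, reference, mapping, lddt_params(),
           backbone_only = TRUE)$score
  # group model chains by their compatible reference set (entity groups)
  key <- apply(compat, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_along(mch), key)
  groups <- groups[nzchar(names(groups))]
  if (!length(groups))
    return(new_chain_mapping(data.frame(model = character(),
                                        reference = character()),
                             mch, rch))
  # candidate assignments per group: injective maps of model members onto
  # the group's reference set
  combn_safe <- function(x, k) {
    if (length(x) == k) return(list(x))
    utils::combn(x, k, simplify = FALSE)
  }
  gen_group <- function(members, refs) {
    k <- min(length(members), length(refs))
    subs <- combn_safe(refs, k)
    mems <- combn_safe(members, k)
    out <- list()
    for (mm in mems) for (ss in subs) {
      pp <- perms_of(ss)
      for (p in pp) out[[length(out) + 1L]] <- cbind(mm, p)
    }
    out
  }
  ref_sets <- lapply(names(groups), function(k)
    as.integer(strsplit(k, ",")[[1]]))
  cand <- mapply(gen_group, groups, ref_sets, SIMPLIFY = FALSE)
  sizes <- vapply(cand, length, 1L)
  total <- prod(sizes)
  build_mapping <- function(choice) {
    tab <- do.call(rbind, mapply(function(cc, i) cc[[i]], cand, choice,
                                 SIMPLIFY = FALSE))
    # joint injectivity on the reference side
    if (anyDuplicated(tab[, 2])) return(NULL)
    pairs <- data.frame(model = mch[tab[, 1]], reference = rch[tab[, 2]],
                        stringsAsFactors = FALSE)
    pairs[order(pairs$model, pairs$reference), , drop = FALSE]
  }
  best <- NULL; best_score <- -Inf
  if (total <= exhaustive_limit) {
    grid <- expand.grid(lapply(sizes, seq_len))
    for (r in seq_len(nrow(grid))) {
      pairs <- build_mapping(as.integer(grid[r, ]))
      if (is.null(pairs)) next
      mp <- new_chain_mapping(pairs, mch, rch)
      sc <- score_fn(mp)
      if (sc > best_score + 1e-12 ||
          (abs(sc - best_score) <= 1e-12 && !is.null(best) &&
           pair_key(pairs) < pair_key(best$pairs))) {
        best <- mp; best_score <- sc
      }
    }
  } else {
    # greedy: pair chains in lexicographic order, then improve by swaps
    pairs <- data.frame(model = character(), reference = character(),
                        stringsAsFactors = FALSE)
    used <- logical(length(rch))
    for (i in order(mch)) {
      avail <- which(compat[i, ] & !used)
      if (!length(avail)) next
      j <- avail[order(rch[avail])][1]
      used[j] <- TRUE
      pairs <- rbind(pairs, data.frame(model = mch[i], reference = rch[j],
                                       stringsAsFactors = FALSE))
    }
    best <- new_chain_mapping(pairs, mch, rch)
    best_score <- score_fn(best)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      np <- nrow(best$pairs)
      for (a in seq_len(np)) for (b in seq_len(np)) {
        if (a >= b) next
        p2 <- best$pairs
        if (!compat[match(p2$model[a], mch), match(p2$reference[b], rch)] ||
            !compat[match(p2$model[b], mch), match(p2$reference[a], rch)])
          next
        tmp <- p2$reference[a]; p2$reference[a] <- p2$reference[b]
        p2$reference[b] <- tmp
        mp <- new_chain_mapping(p2, mch, rch)
        sc <- score_fn(mp)
        if (sc > best_score + 1e-12) {
          best <- mp; best_score <- sc; improved <- TRUE
        }
      }
    }
  }
  best %||% new_chain_mapping(data.frame(model = character(),
                                         reference = character()), mch, rch)
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

pair_key <- function(pairs) paste(pairs$model, pairs$reference, collapse = ";")

new_chain_mapping <- function(pairs, model_chains, reference_chains) {
  stopifnot(!anyDuplicated(pairs$model), !anyDuplicated(pairs$reference))
  structure(list(pairs = pairs,
                 unmapped_model = setdiff(model_chains, pairs$model),
                 unmapped_reference = setdiff(reference_chains,
                                              pairs$reference)),
            class = "chain_mapping")
}

#' Construct a chain mapping by hand
#' @param model,reference character vectors of paired chain IDs.
#' @param model_chains,reference_chains full chain inventories (defaults to
#'   the paired ones).
#' @return a `chain_mapping`.
#' @export
chain_mapping <- function(model, reference, model_chains = model,
                          reference_chains = reference) {
  new_chain_mapping(data.frame(model = model, reference = reference,
                               stringsAsFactors = FALSE),
                    model_chains, reference_chains)
}

#' @export
print.chain_mapping <- function(x, ...) {
  cat("<chain_mapping> ", nrow(x$pairs), " pair(s)\n", sep = "")
  if (nrow(x$pairs))
    cat(paste0("  ", x$pairs$model, " -> ", x$pairs$reference, "\n"), sep = "")
  if (length(x$unmapped_reference))
    cat("  unmapped reference:", paste(x$unmapped_reference, collapse = ", "),
        "\n")
  if (length(x$unmapped_model))
    cat("  unmapped model:", paste(x$unmapped_model, collapse = ", "), "\n")
  invisible(x)
}

## ------------------------------------------------------------------------
## Ligand mapping

#' Map model ligands onto reference ligands
#'
#' Assigns model ligand chains to graph-isomorphic reference ligand chains,
#' maximising the summed pose score. Reference ligands without an
#' isomorphic model ligand stay unmapped (counted as failures downstream).
#'
#' @param model_ligands named list of [ligand_graph()] keyed by model ligand
#'   chain ID.
#' @param reference_ligands named list keyed by reference ligand chain ID.
#' @param pose_score_fn function(model_id, reference_id) -> numeric score;
#'   defaults to 0 for every pair (then the lexicographically first
#'   assignment is returned).
#' @return object of class `ligand_mapping`: `pairs` (data.frame model,
#'   reference), `unmapped_reference`.
#' @export
map_ligands <- function(model_ligands, reference_ligands,
                        pose_score_fn = NULL) {
  if (is.null(pose_score_fn)) pose_score_fn <- function(m, r) 0
  mids <- sort(names(model_ligands)); rids <- sort(names(reference_ligands))
  iso <- matrix(FALSE, length(mids), length(rids), dimnames = list(mids, rids))
  for (m in mids) for (r in rids)
    iso[m, r] <- graphs_isomorphic(model_ligands[[m]], reference_ligands[[r]])
  pairs <- data.frame(model = character(), reference = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (length(mids) && length(rids)) {
    score <- matrix(-Inf, length(mids), length(rids),
                    dimnames = list(mids, rids))
    for (m in mids) for (r in rids)
      if (iso[m, r]) score[m, r] <- pose_score_fn(m, r)
    # small instances: exhaustive over injective assignments per iso class;
    # ligand counts per component are tiny in practice, greedy otherwise
    best <- best_assignment(score)
    if (nrow(best))
      pairs <- data.frame(model = mids[best[, 1]], reference = rids[best[, 2]],
                          score = score[best], stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs,
                 unmapped_reference = setdiff(rids, pairs$reference)),
            class = "ligand_mapping")
}

# Maximise total score over injective partial assignments (pairs with -Inf
# are forbidden). Exhaustive branch-and-bound for <= 8 rows, greedy beyond.
best_assignment <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  if (nr == 0 || nc == 0) return(matrix(integer(), ncol = 2))
  if (nr <= 8 && nc <= 8) {
    best <- NULL; best_sc <- -1
    recurse <- function(row, used, acc, sc) {
      if (row > nr) {
        if (sc > best_sc + 1e-12) { best <<- acc; best_sc <<- sc }
        return()
      }
      for (j in seq_len(nc)) {
        if (used[j] || !is.finite(score[row, j])) next
        used[j] <- TRUE
        recurse(row + 1L, used, rbind(acc, c(row, j)), sc + score[row, j])
        used[j] <- FALSE
      }
      recurse(row + 1L, used, acc, sc)  # leave this model ligand unmapped
    }
    recurse(1L, logical(nc), matrix(integer(), ncol = 2), 0)
    return(best %||% matrix(integer(), ncol = 2))
  }
  out <- matrix(integer(), ncol = 2)
  used <- logical(nc)
  for (i in seq_len(nr)) {
    j <- which(!used & is.finite(score[i, ]))
    if (!length(j)) next
    j <- j[which.max(score[i, j])]
    used[j] <- TRUE
    out <- rbind(out, c(i, j))
  }
  out
}

#' @export
print.ligand_mapping <- function(x, ...) {
  cat("<ligand_mapping> ", nrow(x$pairs), " pair(s)\n", sep = "")
  if (nrow(x$pairs))
    cat(paste0("  ", x$pairs$model, " -> ", x$pairs$reference, "\n"), sep = "")
  if (length(x$unmapped_reference))
    cat("  unmapped reference:", paste(x$unmapped_reference, collapse = ", "),
        "\n")
  invisible(x)
}
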