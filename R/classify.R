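# Target novelty classification from sequence-template evidence:
# redundancy clustering, template measurement, and the easy/medium/hard and
# ligand-target rules.

#' Greedy sequence identity clustering
#'
#' CD-HIT-style incremental clustering: sequences are sorted longest first
#' (ties by ID), each sequence joins the first existing cluster whose
#' founder it matches at or above the identity threshold, computed over the
#' shorter sequence length, otherwise founds a new cluster. Protein
#' sequences cluster at 99% by default; peptides and nucleic acids at 100%.
#' The reported representative of each cluster is its alphabetically first
#' member.
#'
#' @param seqs data.frame with columns `id`, `canonical`, `kind`.
#' @param identity_threshold percent identity in (0, 100]; default 99 for
#'   proteins and 100 otherwise (taken from the first row's kind).
#' @return list of clusters, each a list with `members` (sorted),
#'   `representative` and `cluster_id`.
#' @export
cluster_sequences <- function(seqs, identity_threshold = NULL) {
  if (!nrow(seqs)) return(list())
  stopifnot(all(c("id", "canonical", "kind") %in% names(seqs)))
  if (length(unique(seqs$kind)) > 1)
    stop("all sequences must share a kind; cluster each kind separately")
  if (is.null(identity_threshold))
    identity_threshold <- if (seqs$kind[1] == "protein") 99 else 100
  ord <- order(-nchar(seqs$canonical), seqs$id)
  seqs <- seqs[ord, , drop = FALSE]
  founders <- character(); members <- list()
  for (r in seq_len(nrow(seqs))) {
    sq <- seqs$canonical[r]
    placed <- FALSE
    for (k in seq_along(founders)) {
      if (seq_identity_short(sq, founders[k], seqs$kind[1]) >=
          identity_threshold - 1e-9) {
        members[[k]] <- c(members[[k]], seqs$id[r])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      founders <- c(founders, sq)
      members[[length(members) + 1L]] <- seqs$id[r]
    }
  }
  lapply(seq_along(members), function(k) {
    mm <- sort(members[[k]])
    list(cluster_id = paste0("c", k), members = mm, representative = mm[1])
  })
}

# Percent identity over the shorter sequence length (clustering convention):
# identical residues in the optimal local alignment / min length.
seq_identity_short <- function(a, b, kind = "protein") {
  if (a == b) return(100)
  pa <- align_pair(a, b, kind)
  100 * pa$matches / min(nchar(a), nchar(b))
}

align_pair <- function(a, b, kind = "protein") {
  protein <- kind %in% c("protein", "peptide")
  submat <- if (protein) "BLOSUM62" else
    Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                             baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    if (protein) Biostrings::AAString(a) else Biostrings::DNAString(chartr("U", "T", a)),
    if (protein) Biostrings::AAString(b) else Biostrings::DNAString(chartr("U", "T", b)),
    type = "local", substitutionMatrix = submat,
    gapOpening = 10, gapExtension = 0.5)
  pat <- as.character(Biostrings::pattern(pa))
  list(matches = Biostrings::nmatch(pa),
       aligned_columns = nchar(pat),
       target_start = Biostrings::start(Biostrings::pattern(pa)),
       target_end = Biostrings::end(Biostrings::pattern(pa)),
       target_aligned = nchar(gsub("-", "", pat)))
}

#' Cluster complexes by their sequence-cluster content
#'
#' Two targets share a complex cluster iff they contain the same set of
#' single-sequence clusters (set semantics: stoichiometry of identical
#' sequences is ignored). The representative is the alphabetically first
#' target ID.
#'
#' @param targets list of [target_complex()].
#' @param seq_clusters list of clusters from [cluster_sequences()], whose
#'   members are entity keys of the form `"<target_id>:<entity_id>"`.
#' @return list of clusters (`members`, `representative`, `cluster_id`).
#' @export
cluster_complexes <- function(targets, seq_clusters) {
  ent2cl <- character()
  for (cl in seq_clusters)
    ent2cl[cl$members] <- cl$cluster_id
  keys <- vapply(targets, function(t) {
    ek <- paste0(t$target_id, ":",
                 vapply(t$polymers, function(p) p$entity_id, ""))
    cls <- ent2cl[ek]
    if (anyNA(cls))
      stop("target ", t$target_id, " has entities without a sequence cluster")
    paste(sort(unique(cls)), collapse = "+")
  }, "")
  ids <- vapply(targets, function(t) t$target_id, "")
  lapply(seq_along(unique(keys)), function(k) {
    key <- unique(keys)[k]
    mm <- sort(ids[keys == key])
    list(cluster_id = paste0("x", k), members = mm, representative = mm[1],
         content = key)
  })
}

## ------------------------------------------------------------------------
## Template hits

#' Measure a target-template sequence pair
#'
#' Local alignment (affine gaps; BLOSUM62 for amino acids, a standard
#' match/mismatch matrix for nucleic acids) summarised as a template hit:
#' identity over aligned columns, target coverage, and the uncovered
#' residue count. No e-value is produced by the internal aligner.
#'
#' @param target_seq,template_seq canonical sequences.
#' @param kind sequence kind (`protein`, `peptide`, `dna`, `rna`).
#' @param target_entity,template_id identifiers carried into the hit.
#' @return a template-hit record (list): `target_entity`, `template_id`,
#'   `identity`, `coverage`, `uncovered`, `evalue` (`NA`), `target_length`.
#' @export
align_and_measure <- function(target_seq, template_seq, kind = "protein",
                              target_entity = "target", template_id = "template") {
  stopifnot(nzchar(target_seq), nzchar(template_seq))
  pa <- align_pair(target_seq, template_seq, kind)
  tlen <- nchar(target_seq)
  covered <- pa$target_aligned
  template_hit(target_entity, template_id,
               identity = 100 * pa$matches / pa$aligned_columns,
               coverage = 100 * covered / tlen,
               uncovered = tlen - covered,
               evalue = NA_real_, target_length = tlen)
}

#' Construct a template hit record
#' @param target_entity,template_id identifiers.
#' @param identity,coverage percentages in [0,100].
#' @param uncovered target residues outside the alignment.
#' @param evalue e-value (`NA` when unavailable).
#' @param target_length target sequence length.
#' @return list of class `template_hit`.
#' @export
template_hit <- function(target_entity, template_id, identity, coverage,
                         uncovered, evalue = NA_real_, target_length) {
  stopifnot(identity >= 0, identity <= 100 + 1e-9,
            coverage >= 0, coverage <= 100 + 1e-9)
  structure(list(target_entity = target_entity, template_id = template_id,
                 identity = identity, coverage = coverage,
                 uncovered = as.integer(uncovered), evalue = evalue,
                 target_length = as.integer(target_length)),
            class = "template_hit")
}

#' Parse a tabular hit file
#'
#' Reads the standard 12-column tab-separated hit dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore). Multiple HSPs of one query-template
#' pair are merged by uniting their query coverage intervals; the merged
#' identity is the alignment-length-weighted mean and the merged e-value
#' the minimum.
#'
#' @param path hit table path.
#' @param target_lengths named integer vector or two-column data.frame
#'   (id, length) giving the length of each query sequence.
#' @return list of template-hit records.
#' @export
parse_hit_table <- function(path, target_lengths) {
  if (is.data.frame(target_lengths))
    target_lengths <- stats::setNames(as.integer(target_lengths[[2]]),
                                      target_lengths[[1]])
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("malformed hit table row ", bad[1], ": expected 12 tab-separated ",
         "columns, got ", lengths(fields)[bad[1]])
  m <- do.call(rbind, fields)
  df <- data.frame(query = m[, 1], subject = m[, 2],
                   identity = as.numeric(m[, 3]), alen = as.integer(m[, 4]),
                   qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                   evalue = as.numeric(m[, 11]), stringsAsFactors = FALSE)
  if (anyNA(df$identity) || anyNA(df$qstart) || anyNA(df$qend))
    stop("malformed hit table: non-numeric identity or coordinates")
  out <- list()
  for (key in unique(paste(df$query, df$subject, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- df[df$query == parts[1] & df$subject == parts[2], , drop = FALSE]
    tlen <- target_lengths[[parts[1]]]
    if (is.null(tlen) || is.na(tlen))
      stop("no target length for query '", parts[1], "'")
    covered <- interval_union_size(sub$qstart, sub$qend)
    out[[length(out) + 1L]] <- template_hit(
      parts[1], parts[2],
      identity = sum(sub$identity * sub$alen) / sum(sub$alen),
      coverage = 100 * covered / tlen,
      uncovered = tlen - covered,
      evalue = min(sub$evalue), target_length = tlen)
  }
  out
}

interval_union_size <- function(starts, ends) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  total <- 0L; cur_s <- starts[1]; cur_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= cur_e + 1L) cur_e <- max(cur_e, ends[k])
    else { total <- total + (cur_e - cur_s + 1L); cur_s <- starts[k]; cur_e <- ends[k] }
  }
  total + (cur_e - cur_s + 1L)
}

## ------------------------------------------------------------------------
## Difficulty labels

#' Label one sequence against one template hit
#'
#' Protein rules: "easy" needs identity >= 85%, coverage >= 70%, and, for
#' targets longer than 250 residues, fewer than 45 uncovered residues;
#' "medium" needs identity < 85% but an e-value <= 1e-4 with the same
#' coverage requirements; everything else is "hard". Peptides, DNA and RNA
#' are "easy" only at 100% identity with full coverage, "hard" otherwise.
#' With no hit at all the label is "hard".
#'
#' @param hit a [template_hit()], or `NULL` for "no hit".
#' @param kind sequence kind.
#' @return `"easy"`, `"medium"` or `"hard"`.
#' @export
label_sequence <- function(hit, kind = "protein") {
  if (is.null(hit)) return("hard")
  if (kind %in% c("peptide", "dna", "rna")) {
    easy <- hit$identity >= 100 - 1e-9 && hit$coverage >= 100 - 1e-9
    return(if (easy) "easy" else "hard")
  }
  cov_ok <- hit$coverage >= 70 - 1e-9 &&
    (hit$target_length <= 250 || hit$uncovered < 45)
  if (hit$identity >= 85 - 1e-9 && cov_ok) return("easy")
  if (hit$identity < 85 - 1e-9 && !is.na(hit$evalue) &&
      hit$evalue <= 1e-4 && cov_ok) return("medium")
  "hard"
}

#' Aggregate per-entity labels into a complex label
#'
#' A complex is "easy" if a single template covers all its entities as
#' easy; "medium" if it is not easy but some template is easy or medium for
#' all entities; "hard" when at least one entity only maps to hard
#' templates or no template covers the whole complex. Entities without a
#' hit against a template are implicitly hard for that template.
#'
#' @param target a [target_complex()].
#' @param per_template_labels named list: template_id -> named character
#'   vector entity_id -> label.
#' @return `"easy"`, `"medium"` or `"hard"`.
#' @export
label_complex <- function(target, per_template_labels) {
  entities <- vapply(target$polymers, function(p) p$entity_id, "")
  if (!length(per_template_labels)) return("hard")
  ranks <- c(easy = 1L, medium = 2L, hard = 3L)
  any_easy <- FALSE; any_medium <- FALSE
  for (labels in per_template_labels) {
    lv <- labels[entities]
    lv[is.na(lv)] <- "hard"
    worst <- max(ranks[lv])
    if (worst == 1L) any_easy <- TRUE
    if (worst <= 2L) any_medium <- TRUE
  }
  if (any_easy) "easy" else if (any_medium) "medium" else "hard"
}

#' Detect a ligand target
#'
#' An easy complex is flagged as a "ligand" target when none of its easy
#' templates contains the same set of ligand components as the target.
#' Components on the exclusion list (water by default) are ignored on both
#' sides.
#'
#' @param label complex label; must be `"easy"`.
#' @param target_ligands character vector of target component IDs.
#' @param easy_template_ligand_sets named list: template_id -> character
#'   vector of component IDs (only easy templates).
#' @param exclude component IDs ignored in the comparison.
#' @return `TRUE` when the ligand context is novel.
#' @export
detect_ligand_target <- function(label, target_ligands,
                                 easy_template_ligand_sets,
                                 exclude = "HOH") {
  if (!identical(label, "easy"))
    stop("ligand detection applies to easy targets only")
  tset <- sort(unique(setdiff(target_ligands, exclude)))
  for (ts in easy_template_ligand_sets)
    if (identical(sort(unique(setdiff(ts, exclude))), tset)) return(FALSE)
  TRUE
}

#' Classify a set of targets from a hit list
#'
#' End-to-end classification: per-entity labels for every (template,
#' entity) hit, complex aggregation, and the ligand-target upgrade for easy
#' complexes. Entity keys in the hits must be `"<target_id>:<entity_id>"`.
#'
#' @param targets list of [target_complex()].
#' @param hits list of [template_hit()] records.
#' @param template_ligand_sets named list: template_id -> component IDs
#'   (used for ligand-target detection; missing templates count as
#'   ligand-free).
#' @param exclude_ligands component IDs ignored in ligand-set comparison.
#' @return data.frame: target_id, label, ligand_target (logical), final
#'   (label with easy upgraded to "ligand" where flagged).
#' @export
classify_targets <- function(targets, hits, template_ligand_sets = list(),
                             exclude_ligands = "HOH") {
  hit_ent <- vapply(hits, function(h) h$target_entity, "")
  hit_tpl <- vapply(hits, function(h) h$template_id, "")
  out <- lapply(targets, function(t) {
    entities <- vapply(t$polymers, function(p) p$entity_id, "")
    kinds <- stats::setNames(vapply(t$polymers, function(p) p$kind, ""),
                             entities)
    keys <- paste0(t$target_id, ":", entities)
    rel <- which(hit_ent %in% keys)
    per_template <- list()
    for (tpl in unique(hit_tpl[rel])) {
      labs <- stats::setNames(rep("hard", length(entities)), entities)
      for (k in rel[hit_tpl[rel] == tpl]) {
        ent <- sub("^.*:", "", hit_ent[k])
        lab <- label_sequence(hits[[k]], kinds[[ent]])
        # several hits of one template to one entity: keep the best label
        if (match(lab, c("easy", "medium", "hard")) <
            match(labs[[ent]], c("easy", "medium", "hard")))
          labs[[ent]] <- lab
      }
      per_template[[tpl]] <- labs
    }
    label <- label_complex(t, per_template)
    lig <- FALSE
    if (label == "easy") {
      easy_tpls <- names(per_template)[vapply(per_template, function(lv)
        all(lv[entities] == "easy"), TRUE)]
      easy_sets <- lapply(stats::setNames(nm = easy_tpls), function(tpl)
        template_ligand_sets[[tpl]] %||% character())
      tl <- vapply(t$nonpolymers, function(np) np$component_id, "")
      lig <- detect_ligand_target("easy", tl, easy_sets, exclude_ligands)
    }
    data.frame(target_id = t$target_id, label = label, ligand_target = lig,
               final = if (lig) "ligand" else label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
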