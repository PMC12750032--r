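# Structure container and coordinate-file I/O.
#
# A structure is a flat atom table plus a chain table, the natural R idiom
# for coordinate data (cf. bio3d). Chains of kind "ligand" hold exactly one
# residue whose atoms follow the component-graph atom order.

#' Construct a structure object
#'
#' @param structure_id identifier string.
#' @param atoms data.frame with columns `chain_id`, `resno` (integer, 1-based
#'   position in the target sequence), `comp_id` (chemical component ID),
#'   `atom` (atom name, unique within a residue), `element`, `x`, `y`, `z`,
#'   `is_hetero` (logical).
#' @param chains data.frame with columns `chain_id`, `entity_ref`, `kind`
#'   (one of protein, peptide, dna, rna, ligand). Derived from `atoms` when
#'   omitted.
#' @param assembly_id assembly label, or "".
#' @param meta experiment metadata, see [experiment_meta()].
#' @return an object of class `eval_structure`.
#' @export
eval_structure <- function(structure_id, atoms, chains = NULL,
                           assembly_id = "", meta = experiment_meta()) {
  stopifnot(is_string(structure_id), is.data.frame(atoms))
  need <- c("chain_id", "resno", "comp_id", "atom", "element", "x", "y", "z",
            "is_hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  atoms$resno <- as.integer(atoms$resno)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  bad <- !valid_element(atoms$element)
  if (any(bad))
    stop("invalid element symbol(s): ",
         paste(unique(atoms$element[bad]), collapse = ", "))
  if (is.null(chains)) {
    ids <- unique(atoms$chain_id)
    chains <- data.frame(chain_id = ids, entity_ref = "",
                         kind = ifelse(vapply(ids, function(cid)
                           all(atoms$is_hetero[atoms$chain_id == cid]), TRUE),
                           "ligand", "protein"),
                         stringsAsFactors = FALSE)
  }
  if (anyDuplicated(chains$chain_id)) stop("duplicate chain_id in structure")
  if (!all(atoms$chain_id %in% chains$chain_id))
    stop("atoms reference unknown chains")
  # residue numbers strictly increasing within each chain; atom names unique
  # within each residue
  for (cid in chains$chain_id) {
    sub <- atoms[atoms$chain_id == cid, ]
    rn <- unique(sub$resno)
    if (is.unsorted(rn, strictly = TRUE))
      stop("residue numbers not strictly increasing in chain ", cid)
    dup <- stats::aggregate(sub$atom, by = list(sub$resno),
                            FUN = function(a) anyDuplicated(a) > 0L)
    if (any(dup$x)) stop("duplicate atom names within a residue in chain ", cid)
  }
  structure(list(structure_id = structure_id, assembly_id = assembly_id,
                 atoms = atoms, chains = chains, meta = meta),
            class = "eval_structure")
}

#' Experiment metadata for reference-eligibility decisions
#'
#' @param method one of `"xray"`, `"nmr"`, `"em"`, `"other"`.
#' @param resolution resolution in Angstrom, or `NA` (required for xray/em).
#' @param n_polymer_chains total polymer chain count of the full entry.
#' @param max_copies_single_entity largest copy count of any single entity.
#' @return a list of class `experiment_meta`.
#' @export
experiment_meta <- function(method = "other", resolution = NA_real_,
                            n_polymer_chains = 1L,
                            max_copies_single_entity = 1L) {
  method <- match.arg(method, c("xray", "nmr", "em", "other"))
  if (method %in% c("xray", "em") && is.na(resolution))
    stop("resolution required for method '", method, "'")
  structure(list(method = method, resolution = resolution,
                 n_polymer_chains = as.integer(n_polymer_chains),
                 max_copies_single_entity = as.integer(max_copies_single_entity)),
            class = "experiment_meta")
}

#' @export
print.eval_structure <- function(x, ...) {
  cat("<eval_structure> ", x$structure_id,
      if (nzchar(x$assembly_id)) paste0(" [assembly ", x$assembly_id, "]"), "\n",
      sep = "")
  for (i in seq_len(nrow(x$chains))) {
    cid <- x$chains$chain_id[i]
    sub <- x$atoms[x$atoms$chain_id == cid, ]
    cat(sprintf("  chain %-3s %-8s %4d residues %5d atoms\n", cid,
                x$chains$kind[i], length(unique(sub$resno)), nrow(sub)))
  }
  invisible(x)
}

polymer_chain_ids <- function(s) {
  s$chains$chain_id[s$chains$kind != "ligand"]
}

ligand_chain_ids <- function(s) {
  s$chains$chain_id[s$chains$kind == "ligand"]
}

chain_atoms <- function(s, chain_id, heavy_only = FALSE) {
  a <- s$atoms[s$atoms$chain_id == chain_id, , drop = FALSE]
  if (heavy_only) a <- a[a$element != "H", , drop = FALSE]
  a
}

# One-letter sequence of a polymer chain from its component IDs.
chain_sequence <- function(s, chain_id, parent_map = component_parents()) {
  sub <- chain_atoms(s, chain_id)
  comp <- sub$comp_id[!duplicated(sub$resno)]
  derive_canonical(comp, parent_map)$canonical
}

#' Drop chains from a structure
#' @param s an `eval_structure`.
#' @param chain_ids chains to remove.
#' @return the reduced structure.
#' @export
drop_chains <- function(s, chain_ids) {
  keep <- !(s$chains$chain_id %in% chain_ids)
  if (!any(keep)) stop("cannot drop every chain")
  eval_structure(s$structure_id,
                 s$atoms[!(s$atoms$chain_id %in% chain_ids), , drop = FALSE],
                 s$chains[keep, , drop = FALSE],
                 assembly_id = s$assembly_id, meta = s$meta)
}

## ------------------------------------------------------------------------
## Reading

#' Read a coordinate file
#'
#' Reads a structure in mmCIF (PDBx `atom_site` loop) or PDB dialect.
#' Alternate locations are reduced to the highest-occupancy conformer (ties
#' broken by altloc letter order). Ligand (HETATM, non-water) components
#' become single-residue chains of kind `"ligand"`. PDB files lacking an
#' element column have elements inferred from atom names.
#'
#' @param path file path.
#' @param format `"mmcif"` or `"pdb"`; guessed from the extension by default.
#' @param allow_insertion_codes insertion codes are accepted (and the chain
#'   renumbered sequentially) when `TRUE`, as for experimental references;
#'   model files must follow 1-based target numbering and are rejected.
#' @return an [eval_structure()].
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           allow_insertion_codes = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (format == "mmcif") read_mmcif(path, allow_insertion_codes)
  else read_pdb_dialect(path, allow_insertion_codes)
}

# Minimal PDBx atom_site loop parser. Only the atom_site category is
# consumed; tags may appear in any order.
read_mmcif <- function(path, allow_insertion_codes = TRUE) {
  lines <- readLines(path, warn = FALSE)
  sid <- sub("^data_", "", grep("^data_", lines, value = TRUE)[1])
  if (is.na(sid)) sid <- basename(path)
  i <- 1L; n <- length(lines)
  tags <- character(); rows <- list()
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L; tg <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tg <- c(tg, trimws(lines[j])); j <- j + 1L
      }
      if (any(grepl("^_atom_site\\.", tg))) {
        tags <- sub("^_atom_site\\.", "", tg)
        while (j <= n && !grepl("^\\s*(#|loop_|_|data_)", lines[j]) &&
               nzchar(trimws(lines[j]))) {
          rows[[length(rows) + 1L]] <- lines[j]; j <- j + 1L
        }
        i <- j
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows))
    stop("mmCIF parse failure: no atom_site loop found in ", path)
  fields <- strsplit(trimws(unlist(rows)), "\\s+")
  bad <- which(lengths(fields) != length(tags))
  if (length(bad))
    stop("mmCIF parse failure at atom_site record ", bad[1],
         ": expected ", length(tags), " fields")
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  getcol <- function(nm, alt = NULL) {
    if (nm %in% tags) m[, nm]
    else if (!is.null(alt) && alt %in% tags) m[, alt]
    else NULL
  }
  grp <- getcol("group_PDB") %||% rep("ATOM", nrow(m))
  comp <- getcol("label_comp_id", "auth_comp_id")
  atom <- gsub('"', "", getcol("label_atom_id", "auth_atom_id"))
  chain <- getcol("auth_asym_id", "label_asym_id")
  entity <- getcol("label_entity_id") %||% rep("", nrow(m))
  seqid <- getcol("auth_seq_id", "label_seq_id")
  ins <- getcol("pdbx_PDB_ins_code") %||% rep("?", nrow(m))
  alt <- getcol("label_alt_id") %||% rep(".", nrow(m))
  occ <- suppressWarnings(as.numeric(getcol("occupancy") %||% rep("1", nrow(m))))
  elem <- getcol("type_symbol")
  x <- as.numeric(getcol("Cartn_x")); y <- as.numeric(getcol("Cartn_y"))
  z <- as.numeric(getcol("Cartn_z"))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("mmCIF parse failure: non-numeric coordinates")
  model_num <- getcol("pdbx_PDB_model_num")
  keep <- if (is.null(model_num)) rep(TRUE, nrow(m)) else model_num == model_num[1]
  at <- data.frame(chain_id = chain, resno = suppressWarnings(as.integer(seqid)),
                   comp_id = comp, atom = atom,
                   element = if (is.null(elem)) NA_character_ else elem,
                   x = x, y = y, z = z,
                   is_hetero = grp == "HETATM",
                   altloc = ifelse(alt %in% c(".", "?"), "", alt),
                   ins = ifelse(ins %in% c(".", "?"), "", ins),
                   occ = ifelse(is.na(occ), 1, occ),
                   entity_ref = entity, stringsAsFactors = FALSE)[keep, ]
  finish_atoms(at, sid, allow_insertion_codes)
}

read_pdb_dialect <- function(path, allow_insertion_codes = TRUE) {
  p <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                verbose = FALSE),
                error = function(e) stop("PDB parse failure in ", path, ": ",
                                         conditionMessage(e)))
  a <- p$atom
  elem <- a$elesy
  no_elem <- is.na(elem) | !nzchar(trimws(elem))
  if (any(no_elem))
    elem[no_elem] <- mapply(infer_element, a$elety[no_elem],
                            a$type[no_elem] == "HETATM")
  at <- data.frame(chain_id = a$chain, resno = a$resno, comp_id = a$resid,
                   atom = a$elety, element = trimws(elem),
                   x = a$x, y = a$y, z = a$z,
                   is_hetero = a$type == "HETATM",
                   altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
                   ins = ifelse(is.na(a$insert) | a$insert == "", "", a$insert),
                   occ = ifelse(is.na(a$o), 1, a$o),
                   entity_ref = "", stringsAsFactors = FALSE)
  sid <- sub("\\.[^.]*$", "", basename(path))
  finish_atoms(at, sid, allow_insertion_codes)
}

# Shared post-processing: altloc reduction, water removal, insertion codes,
# ligand chain splitting, chain-table construction.
finish_atoms <- function(at, sid, allow_insertion_codes) {
  at <- at[at$comp_id != "HOH", , drop = FALSE]
  if (!nrow(at)) stop("structure contains no non-water atoms")
  # altlocs: keep the highest-occupancy conformer per atom, ties by letter
  if (any(nzchar(at$altloc))) {
    key <- paste(at$chain_id, at$resno, at$ins, at$atom, sep = "\r")
    ord <- order(key, -at$occ, at$altloc)
    at <- at[ord, ][!duplicated(key[ord]), ]
  }
  if (any(nzchar(at$ins))) {
    if (!allow_insertion_codes)
      stop("insertion codes present; model files must be numbered 1-based ",
           "against the target sequence")
    # renumber each chain sequentially in file order
    for (cid in unique(at$chain_id)) {
      idx <- which(at$chain_id == cid)
      rk <- paste(at$resno[idx], at$ins[idx], sep = "\r")
      at$resno[idx] <- as.integer(factor(rk, levels = unique(rk)))
    }
  }
  at$ins <- NULL; at$altloc <- NULL; at$occ <- NULL
  # hetero components become their own single-residue ligand chains
  poly <- at[!at$is_hetero, , drop = FALSE]
  het <- at[at$is_hetero, , drop = FALSE]
  chains <- data.frame(chain_id = character(), entity_ref = character(),
                       kind = character(), stringsAsFactors = FALSE)
  out <- list()
  if (nrow(poly)) {
    if (anyNA(poly$resno)) stop("polymer atoms without residue numbers")
    out[[length(out) + 1L]] <- poly
    for (cid in unique(poly$chain_id)) {
      sub <- poly[poly$chain_id == cid, ]
      comp <- sub$comp_id[!duplicated(sub$resno)]
      kind <- guess_chain_kind(comp)
      chains <- rbind(chains, data.frame(
        chain_id = cid, entity_ref = sub$entity_ref[1], kind = kind,
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(het)) {
    grp <- paste(het$chain_id, het$resno, sep = "\r")
    k <- 0L
    for (g in unique(grp)) {
      k <- k + 1L
      sub <- het[grp == g, , drop = FALSE]
      new_id <- paste0(sub$chain_id[1], "_L", k)
      sub$chain_id <- new_id
      sub$resno <- 1L
      out[[length(out) + 1L]] <- sub
      chains <- rbind(chains, data.frame(
        chain_id = new_id, entity_ref = sub$entity_ref[1], kind = "ligand",
        stringsAsFactors = FALSE))
    }
  }
  at <- do.call(rbind, out)
  at$entity_ref <- NULL
  eval_structure(sid, at, chains)
}

.amino3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.dna1 <- c(DA = "A", DC = "C", DG = "G", DT = "T")
.rna1 <- c(A = "A", C = "C", G = "G", U = "U")

guess_chain_kind <- function(comp_ids) {
  pm <- component_parents()
  cls <- pm$class[match(comp_ids, pm$component_id)]
  cls[is.na(cls)] <- "amino"   # unknown components default to amino here
  if (all(cls %in% c("nucleic-dna"))) return("dna")
  if (all(cls %in% c("nucleic-rna"))) return("rna")
  if (length(comp_ids) < 30) "peptide" else "protein"
}

## ------------------------------------------------------------------------
## Writing

#' Write a structure to disk
#'
#' Writes the coordinate content of a structure as a minimal mmCIF
#' `atom_site` loop or in PDB dialect. Coordinates are written at the PDB
#' precision of 0.001 Angstrom.
#'
#' @param s an [eval_structure()].
#' @param path output path.
#' @param format `"mmcif"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("mmcif", "pdb")) {
  format <- match.arg(format)
  a <- s$atoms
  # PDB has one-character chain IDs: reuse them where possible, otherwise
  # allocate from a fixed pool (deterministic)
  ids <- s$chains$chain_id
  pool <- c(LETTERS, letters, as.character(0:9))
  pdb_id <- character(length(ids))
  for (k in seq_along(ids)) {
    cand <- substr(ids[k], 1, 1)
    if (!cand %in% pdb_id && nchar(ids[k]) == 1) pdb_id[k] <- cand
  }
  for (k in which(!nzchar(pdb_id))) {
    cand <- setdiff(pool, pdb_id)[1]
    if (is.na(cand)) stop("too many chains for PDB output")
    pdb_id[k] <- cand
  }
  out_chain <- pdb_id[match(a$chain_id, ids)]
  if (format == "mmcif") {
    hdr <- c(paste0("data_", s$structure_id), "#", "loop_",
             paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                     "label_atom_id", "label_alt_id",
                                     "label_comp_id", "auth_asym_id",
                                     "label_entity_id", "auth_seq_id",
                                     "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                                     "Cartn_z", "occupancy", "B_iso_or_equiv",
                                     "pdbx_PDB_model_num")))
    ent <- s$chains$entity_ref[match(a$chain_id, s$chains$chain_id)]
    ent[!nzchar(ent)] <- "?"
    recs <- sprintf("%s %d %s %s . %s %s %s %d ? %.3f %.3f %.3f 1.00 0.00 1",
                    ifelse(a$is_hetero, "HETATM", "ATOM"), seq_len(nrow(a)),
                    a$element, a$atom, a$comp_id, a$chain_id, ent, a$resno,
                    a$x, a$y, a$z)
    writeLines(c(hdr, recs, "#"), path)
  } else {
    nm <- a$atom
    pad <- ifelse(nchar(nm) < 4 & nchar(a$element) == 1,
                  paste0(" ", nm), nm)
    recs <- sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    ifelse(a$is_hetero, "HETATM", "ATOM"), seq_len(nrow(a)),
                    substr(pad, 1, 4), a$comp_id, out_chain,
                    a$resno, a$x, a$y, a$z, 1, 0, a$element)
    writeLines(c(recs, "END"), path)
  }
  invisible(path)
}

## ------------------------------------------------------------------------
## Sequences and eligibility

#' Table of chemical components and their parents
#'
#' Returns the bundled table mapping component IDs to a parent standard
#' residue, a one-letter code, and a polymer class. The bundled table covers
#' the standard amino acids and nucleotides plus common modified residues
#' (e.g. MSE to MET, SEP to SER, PSU to U); a fuller dictionary extract can
#' be supplied as a TSV with the same columns.
#'
#' @param path optional TSV (component_id, parent, one_letter, class) to use
#'   instead of the bundled table. `class` is `amino`, `nucleic-dna`,
#'   `nucleic-rna`, `unknown`, or `non-linking`.
#' @return data.frame with those columns.
#' @export
component_parents <- local({
  cache <- NULL
  function(path = NULL) {
    if (!is.null(path))
      return(utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character"))
    if (is.null(cache)) {
      f <- system.file("extdata", "component_parents.tsv",
                       package = "complexeval", mustWork = TRUE)
      cache <<- utils::read.delim(f, stringsAsFactors = FALSE,
                                  colClasses = "character")
    }
    cache
  }
})

#' Derive a canonical sequence from component IDs
#'
#' Modified residues are replaced by their parent standard residue using the
#' component dictionary table. Sequences containing components marked
#' unknown or non-linking, components without a parent (orphans), or a mix
#' of amino and nucleic parents are flagged invalid.
#'
#' @param noncanonical_seq character vector of component IDs.
#' @param parent_map table from [component_parents()].
#' @return list with `canonical` (one-letter string, "" when invalid),
#'   `valid` (logical) and `reason`.
#' @export
derive_canonical <- function(noncanonical_seq, parent_map = component_parents()) {
  if (!length(noncanonical_seq)) stop("empty sequence")
  idx <- match(noncanonical_seq, parent_map$component_id)
  if (anyNA(idx)) {
    bad <- unique(noncanonical_seq[is.na(idx)])
    return(list(canonical = "", valid = FALSE,
                reason = paste0("component(s) without a dictionary parent: ",
                                paste(bad, collapse = ", "))))
  }
  cls <- parent_map$class[idx]
  if (any(cls == "unknown"))
    return(list(canonical = "", valid = FALSE,
                reason = paste0("residue(s) marked unknown: ",
                                paste(unique(noncanonical_seq[cls == "unknown"]),
                                      collapse = ", "))))
  if (any(cls == "non-linking"))
    return(list(canonical = "", valid = FALSE,
                reason = paste0("non-linking residue(s): ",
                                paste(unique(noncanonical_seq[cls == "non-linking"]),
                                      collapse = ", "))))
  top <- ifelse(cls == "amino", "amino", "nucleic")
  if (length(unique(top)) > 1)
    return(list(canonical = "", valid = FALSE,
                reason = "mix of nucleic and amino acid residues"))
  list(canonical = paste(parent_map$one_letter[idx], collapse = ""),
       valid = TRUE, reason = "")
}

#' Classify a polymer entity from its canonical sequence
#'
#' Amino-acid sequences of 30 residues or more are proteins; shorter ones
#' are peptides. Nucleic sequences are typed by their alphabet class.
#'
#' @param canonical one-letter canonical sequence.
#' @param alphabet_class `"amino"`, `"nucleic-dna"` or `"nucleic-rna"`.
#' @return one of `"protein"`, `"peptide"`, `"dna"`, `"rna"`.
#' @export
classify_entity_kind <- function(canonical,
                                 alphabet_class = c("amino", "nucleic-dna",
                                                    "nucleic-rna")) {
  if (!is_string(canonical) || !nzchar(canonical))
    stop("invalid canonical sequence")
  alphabet_class <- match.arg(alphabet_class)
  switch(alphabet_class,
         amino = if (nchar(canonical) >= 30) "protein" else "peptide",
         `nucleic-dna` = "dna",
         `nucleic-rna` = "rna")
}

#' Decide whether an experimental structure may serve as reference
#'
#' References must come from solution NMR, X-ray diffraction, or EM at a
#' resolution of 4.0 Angstrom or better, and very large complexes (more than
#' 200 polymer chains in total, or more than 100 copies of a single entity)
#' are excluded.
#'
#' @param meta an [experiment_meta()].
#' @return list with `eligible` (logical) and `reason` ("" when eligible).
#' @export
reference_eligible <- function(meta) {
  if (meta$method == "other")
    return(list(eligible = FALSE, reason = "unsupported experimental method"))
  if (meta$method == "em" && !(meta$resolution <= 4.0))
    return(list(eligible = FALSE,
                reason = sprintf("EM resolution %.2f A exceeds 4.0 A",
                                 meta$resolution)))
  if (meta$n_polymer_chains > 200)
    return(list(eligible = FALSE,
                reason = sprintf("%d polymer chains exceeds 200",
                                 meta$n_polymer_chains)))
  if (meta$max_copies_single_entity > 100)
    return(list(eligible = FALSE,
                reason = sprintf("%d copies of one entity exceeds 100",
                                 meta$max_copies_single_entity)))
  list(eligible = TRUE, reason = "")
}
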