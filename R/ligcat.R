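# Ligand categorization: drug-like / cofactor / ion / artifact / other.

#' Compute ligand descriptors from SMILES
#'
#' Heavy-atom count, molecular weight, hydrogen-bond donors/acceptors and
#' logP via the cheminformatics backend (Open Babel through ChemmineR).
#' SMILES are canonicalized by the backend first, so kekulized and aromatic
#' dialects give identical descriptors.
#'
#' @param smiles SMILES string.
#' @param component_id optional component ID carried along.
#' @param pdb_occurrence number of PDB entries containing the component
#'   (from an occurrence table; left `NA` when unknown).
#' @return list of class `ligand_descriptors`: `component_id`,
#'   `mol_weight` (Da), `hbd`, `hba`, `logp`, `heavy_atoms`,
#'   `pdb_occurrence`.
#' @export
descriptors_from_smiles <- function(smiles, component_id = "",
                                    pdb_occurrence = NA_integer_) {
  g <- ligand_graph(smiles)   # validates and gives the heavy-atom count
  if (length(g$elements) == 1 && nrow(g$bonds) == 0) {
    # monoatomic species: Open Babel property calculation is meaningless
    w <- .atomic_weights[g$elements]
    if (is.na(w)) stop("unknown element in SMILES: ", smiles)
    return(structure(list(component_id = component_id, mol_weight = unname(w),
                          hbd = 0L, hba = 0L, logp = 0,
                          heavy_atoms = 1L,
                          pdb_occurrence = as.integer(pdb_occurrence)),
                     class = "ligand_descriptors"))
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  pr <- ChemmineR::propOB(sdf)
  structure(list(component_id = component_id,
                 mol_weight = as.numeric(pr$MW[1]),
                 hbd = as.integer(pr$HBD[1]),
                 hba = as.integer(pr$HBA1[1]),
                 logp = as.numeric(pr$logP[1]),
                 heavy_atoms = length(g$elements),
                 pdb_occurrence = as.integer(pdb_occurrence)),
            class = "ligand_descriptors")
}

.atomic_weights <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     F = 18.998, NA. = 22.990, MG = 24.305, P = 30.974,
                     S = 32.06, CL = 35.45, K = 39.098, CA = 40.078,
                     MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
                     CU = 63.546, ZN = 65.38, BR = 79.904, I = 126.90,
                     CD = 112.41, HG = 200.59, SR = 87.62, CS = 132.91,
                     BA = 137.33, LI = 6.94, RB = 85.468)
names(.atomic_weights)[names(.atomic_weights) == "NA."] <- "NA"

#' Lipinski rule-of-five test
#'
#' Default variant requires all four criteria: molecular weight < 500 Da,
#' at most 5 hydrogen-bond donors, at most 10 acceptors, logP <= 5. The
#' classic variant tolerating one violation is available via
#' `max_violations = 1`.
#'
#' @param d a [descriptors_from_smiles()] result (or compatible list).
#' @param max_violations violations tolerated (0 = strict all-four).
#' @return logical.
#' @export
lipinski_pass <- function(d, max_violations = 0L) {
  viol <- sum(!(d$mol_weight < 500), !(d$hbd <= 5), !(d$hba <= 10),
              !(d$logp <= 5))
  viol <= max_violations
}

#' Load ligand category lists
#'
#' Reads plain-text component-ID lists (one per line, `#` comments) for the
#' ion, cofactor and artifact categories. The bundled lists cover common
#' cases; pass a directory with `ions.txt`, `cofactors.txt`,
#' `artifacts.txt` to override. Overlap between the lists is rejected.
#'
#' @param dir directory containing the three list files.
#' @return list of class `category_lists` with `ions`, `cofactors`,
#'   `artifacts` character vectors.
#' @export
category_lists <- function(dir = system.file("extdata", package = "complexeval")) {
  rd <- function(f) {
    x <- readLines(file.path(dir, f), warn = FALSE)
    x <- trimws(sub("#.*$", "", x))
    unique(x[nzchar(x)])
  }
  out <- list(ions = rd("ions.txt"), cofactors = rd("cofactors.txt"),
              artifacts = rd("artifacts.txt"))
  ov <- c(intersect(out$ions, out$cofactors),
          intersect(out$ions, out$artifacts),
          intersect(out$cofactors, out$artifacts))
  if (length(ov))
    stop("category lists overlap: ", paste(unique(ov), collapse = ", "))
  structure(out, class = "category_lists")
}

#' Categorize a ligand
#'
#' Assigns exactly one of ion, cofactor, artifact, drug-like, or other.
#' List membership takes precedence (ion, then cofactor, then artifact);
#' remaining ligands are drug-like when they satisfy the Lipinski test and
#' appear in fewer than 100 PDB entries, otherwise "other" (metabolites,
#' sugars, lipids, ...). An unknown occurrence count is treated as rare.
#'
#' @param d a [descriptors_from_smiles()] result.
#' @param lists a [category_lists()] object.
#' @param occurrence_limit drug-like requires `pdb_occurrence` strictly
#'   below this.
#' @param max_violations passed to [lipinski_pass()].
#' @return one of `"ion"`, `"cofactor"`, `"artifact"`, `"drug_like"`,
#'   `"other"`.
#' @export
categorize <- function(d, lists = category_lists(), occurrence_limit = 100L,
                       max_violations = 0L) {
  id <- d$component_id
  if (id %in% lists$ions) return("ion")
  if (id %in% lists$cofactors) return("cofactor")
  if (id %in% lists$artifacts) return("artifact")
  occ <- d$pdb_occurrence
  rare <- is.na(occ) || occ < occurrence_limit
  if (lipinski_pass(d, max_violations) && rare) return("drug_like")
  "other"
}

#' Categorize a table of ligands
#'
#' @param smiles_table data.frame with columns `component_id`, `smiles`.
#' @param occurrence named integer vector or data.frame (component_id,
#'   count) of PDB occurrence counts.
#' @param lists a [category_lists()].
#' @return the input table with `category` and descriptor columns added.
#' @export
categorize_table <- function(smiles_table, occurrence = NULL,
                             lists = category_lists()) {
  if (is.data.frame(occurrence))
    occurrence <- stats::setNames(as.integer(occurrence[[2]]),
                                  occurrence[[1]])
  rows <- lapply(seq_len(nrow(smiles_table)), function(i) {
    id <- smiles_table$component_id[i]
    occ <- if (!is.null(occurrence) && id %in% names(occurrence))
      occurrence[[id]] else NA_integer_
    d <- descriptors_from_smiles(smiles_table$smiles[i], id, occ)
    data.frame(component_id = id, smiles = smiles_table$smiles[i],
               mol_weight = d$mol_weight, hbd = d$hbd, hba = d$hba,
               logp = d$logp, heavy_atoms = d$heavy_atoms,
               pdb_occurrence = occ, category = categorize(d, lists),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
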