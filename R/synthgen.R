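# Deterministic synthetic fixtures: idealized complexes with known geometry,
# perturbed models with known expected score relations, and a
# classification battery with independently transcribed expected labels.
# Geometry is idealized (helical CA/CB/O traces, analytic ligand shapes) —
# sufficient because every score is purely geometric.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic complex fixture
#'
#' @param seed integer seed; the same spec always yields byte-identical
#'   output.
#' @param n_entities number of distinct polymer entities.
#' @param copies_per_entity integer vector (recycled) of chain copies.
#' @param chain_length residues per chain.
#' @param ligands character vector of ligand SMILES (each placed once; see
#'   `ligand_copies`). Supported geometries: single-atom species,
#'   `"O"`, `"CCO"`, `"CC(=O)O"`, `"c1ccccc1"`.
#' @param ligand_copies copies per ligand entity (recycled).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_entities = 1L, copies_per_entity = 1L,
                         chain_length = 30L, ligands = character(),
                         ligand_copies = 1L) {
  structure(list(seed = as.integer(seed), n_entities = as.integer(n_entities),
                 copies_per_entity = rep_len(as.integer(copies_per_entity),
                                             n_entities),
                 chain_length = as.integer(chain_length),
                 ligands = ligands,
                 ligand_copies = if (length(ligands))
                   rep_len(as.integer(ligand_copies), length(ligands))
                 else integer()),
            class = "fixture_spec")
}

.helix <- function(n, r = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  i <- seq_len(n) - 1L
  ca <- cbind(r * cos(turn * i), r * sin(turn * i), rise * i)
  rad <- cbind(cos(turn * i), sin(turn * i), 0)
  zoff <- matrix(rep(c(0, 0, 1.23), each = n), n, 3)
  list(ca = ca, cb = ca + 1.5 * rad, o = ca + zoff + 0.3 * rad)
}

.ligand_geometry <- function(smiles) {
  g <- ligand_graph(smiles)
  xyz <- switch(smiles,
    "O" = matrix(0, 1, 3),
    "CCO" = rbind(c(0, 0, 0), c(1.52, 0, 0),
                  c(1.52 + 1.43 * cos(1.231), 1.43 * sin(1.231), 0)),
    "CC(=O)O" = rbind(c(0, 0, 0), c(1.52, 0, 0),
                      c(2.145, 1.083, 0), c(2.145, -1.083, 0)),
    "c1ccccc1" = {
      a <- (seq_len(6) - 1) * pi / 3
      cbind(1.39 * cos(a), 1.39 * sin(a), 0)
    },
    {
      if (length(g$elements) == 1) matrix(0, 1, 3)
      else stop("no analytic geometry for SMILES '", smiles,
                "'; supported: single atoms, O, CCO, CC(=O)O, c1ccccc1")
    })
  list(graph = g, xyz = xyz)
}

.amino1to3 <- stats::setNames(names(.amino3), .amino3)

#' Generate a synthetic reference complex
#'
#' Builds an idealized complex: every polymer chain is a helical trace
#' (CA, CB, O atoms per residue) with copies of one entity placed by rigid
#' translation, adjacent chains in contact; each ligand is placed against a
#' chain surface so that at least 3 polymer residues lie within 4 Angstrom.
#' Fully deterministic under the spec seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `reference` ([eval_structure()]) and `target`
#'   ([target_complex()]).
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n_chains <- sum(spec$copies_per_entity)
    # sequences as three-letter component vectors
    seq1 <- vapply(seq_len(spec$n_entities), function(e)
      paste(sample(.amino3, spec$chain_length, replace = TRUE), collapse = ""),
      "")
    comp_seqs <- lapply(seq1, function(s)
      unname(.amino1to3[strsplit(s, "")[[1]]]))

    geo <- .helix(spec$chain_length)
    atoms <- list(); chains <- list()
    chain_letters <- make.unique(rep(LETTERS, length.out = n_chains), sep = "")
    ci <- 0L
    for (e in seq_len(spec$n_entities)) {
      for (cp in seq_len(spec$copies_per_entity[e])) {
        ci <- ci + 1L
        off <- c(11 * (ci - 1L), 0, 0)
        cid <- chain_letters[ci]
        for (rr in seq_len(spec$chain_length)) {
          atoms[[length(atoms) + 1L]] <- data.frame(
            chain_id = cid, resno = rr, comp_id = comp_seqs[[e]][rr],
            atom = c("CA", "CB", "O"),
            element = c("C", "C", "O"),
            x = c(geo$ca[rr, 1], geo$cb[rr, 1], geo$o[rr, 1]) + off[1],
            y = c(geo$ca[rr, 2], geo$cb[rr, 2], geo$o[rr, 2]) + off[2],
            z = c(geo$ca[rr, 3], geo$cb[rr, 3], geo$o[rr, 3]) + off[3],
            is_hetero = FALSE, stringsAsFactors = FALSE)
        }
        chains[[length(chains) + 1L]] <- data.frame(
          chain_id = cid, entity_ref = paste0("p", e),
          kind = if (spec$chain_length >= 30) "protein" else "peptide",
          stringsAsFactors = FALSE)
      }
    }
    poly_atoms <- do.call(rbind, atoms)

    lig_ci <- 0L
    nonpolymers <- list()
    for (li in seq_along(spec$ligands)) {
      lg <- .ligand_geometry(spec$ligands[li])
      comp_id <- sprintf("LG%d", li)
      nonpolymers[[li]] <- nonpolymer_entity(paste0("n", li), comp_id,
                                             spec$ligands[li],
                                             spec$ligand_copies[li])
      for (cp in seq_len(spec$ligand_copies[li])) {
        lig_ci <- lig_ci + 1L
        host <- ((lig_ci - 1L) %% n_chains) + 1L
        anchor_res <- 6L + 6L * ((lig_ci - 1L) %/% n_chains)
        if (anchor_res + 2L > spec$chain_length)
          stop("chain too short to place ligand copies")
        placed <- place_ligand(lg$xyz, poly_atoms,
                               host_chain = chain_letters[host],
                               anchor_res = anchor_res)
        cid <- sprintf("L%d", lig_ci)
        atoms[[length(atoms) + 1L]] <- data.frame(
          chain_id = cid, resno = 1L, comp_id = comp_id,
          atom = paste0(lg$graph$elements, seq_along(lg$graph$elements)),
          element = lg$graph$elements,
          x = placed[, 1], y = placed[, 2], z = placed[, 3],
          is_hetero = TRUE, stringsAsFactors = FALSE)
        chains[[length(chains) + 1L]] <- data.frame(
          chain_id = cid, entity_ref = paste0("n", li), kind = "ligand",
          stringsAsFactors = FALSE)
      }
    }
    reference <- eval_structure("synthetic", do.call(rbind, atoms),
                                do.call(rbind, chains), assembly_id = "1",
                                meta = experiment_meta("xray", 1.5,
                                                       n_polymer_chains = n_chains))
    polymers <- lapply(seq_len(spec$n_entities), function(e)
      polymer_entity(paste0("p", e), comp_seqs[[e]],
                     spec$copies_per_entity[e]))
    list(reference = reference,
         target = target_complex("synthetic", polymers, nonpolymers))
  })
}

# Place a ligand against the helix surface: centred over the local triangle
# of CB atoms (anchor residue and the two residues one helical turn up),
# plane facing the chain, pushed outward until no polymer atom is closer
# than 2 A while >= 3 residues keep an atom within 4 A.
place_ligand <- function(lig_xyz, poly_atoms, host_chain, anchor_res) {
  ha <- poly_atoms[poly_atoms$chain_id == host_chain, ]
  cb <- function(rr) unlist(ha[ha$resno == rr & ha$atom == "CB",
                               c("x", "y", "z")])
  tri <- rbind(cb(anchor_res), cb(anchor_res + 3L), cb(anchor_res + 4L))
  center <- colMeans(tri)
  axis_pt <- c(mean(ha$x[ha$atom == "CA"]), mean(ha$y[ha$atom == "CA"]),
               center[3])
  outward <- center - axis_pt
  outward[3] <- 0
  outward <- outward / sqrt(sum(outward^2))
  # rotate the ligand plane normal (0,0,1) onto the outward direction
  rot <- rotation_onto(c(0, 0, 1), outward)
  oriented <- sweep(lig_xyz, 2, colMeans(lig_xyz)) %*% t(rot)
  pxyz <- as.matrix(poly_atoms[, c("x", "y", "z")])
  res_key <- paste(poly_atoms$chain_id, poly_atoms$resno)
  for (offset in seq(0, 3, by = 0.25)) {
    cand <- sweep(oriented, 2, center + offset * outward, "+")
    d <- cross_dist(pxyz, cand)
    if (min(d) < 2.0) next
    n_close <- length(unique(res_key[apply(d <= 4.0, 1, any)]))
    if (n_close >= 3) return(cand)
  }
  stop("could not place ligand near chain ", host_chain,
       " residue ", anchor_res)
}

# Unit displacement directions (one per point) whose sum and whose
# cross-covariance with the centered points both vanish, found by
# alternating projection between the linear constraint space and the
# product of unit spheres.
displacement_field <- function(xyz, seed = 1L, tol = 1e-13) {
  n <- nrow(xyz)
  if (n < 8) stop("need at least 8 points for a constrained field")
  xc <- sweep(xyz, 2, colMeans(xyz))
  basis <- qr.Q(qr(cbind(1, xc)))   # span{1, centered coords}
  project <- function(u) u - basis %*% crossprod(basis, u)
  u <- with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  for (it in 1:500) {
    u <- project(u)
    nr <- sqrt(rowSums(u^2))
    if (any(nr < 1e-8)) { u[nr < 1e-8, ] <- 1 / sqrt(3); nr <- sqrt(rowSums(u^2)) }
    u <- u / nr
    res <- max(abs(colSums(u)), abs(crossprod(u, xc)))
    if (res < tol) break
  }
  if (res >= 1e-9) stop("displacement field did not converge")
  u / sqrt(rowSums(u^2))
}

# Proper rotation taking unit vector a onto unit vector b (Rodrigues).
rotation_onto <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Derive a perturbed model from a reference
#'
#' Applies one exactly specified perturbation, giving a model with known
#' expected score relations: `none` scores perfectly; a `rigid_shift` of
#' the whole complex leaves LDDT at 1 and BiSyRMSD at 0; a `rigid_shift`
#' of a single chain beyond the largest LDDT threshold drives the
#' interface LDDT to 0; `drop_chain` lowers LDDT while the mapped LDDT
#' stays 1.
#'
#' @param reference an [eval_structure()] from [make_complex()].
#' @param perturbation a list: `list(type = "none")`,
#'   `list(type = "rigid_shift", d = 5, chains = NULL, direction = c(1,0,0))`,
#'   `list(type = "per_atom_noise", sigma = 0.3, seed = 1)`,
#'   `list(type = "drop_chain", k = 1)` (drops the last k polymer chains),
#'   `list(type = "drop_ligand", k = 1)`, or
#'   `list(type = "swap_chain_labels")` (first two chains of one entity).
#' @return the model [eval_structure()].
#' @export
make_model <- function(reference, perturbation = list(type = "none")) {
  s <- reference
  s$structure_id <- paste0(s$structure_id, "_model")
  type <- perturbation$type %||% "none"
  switch(type,
    none = s,
    rigid_shift = {
      d <- perturbation$d %||% 5
      dir <- perturbation$direction %||% c(1, 0, 0)
      dir <- dir / sqrt(sum(dir^2))
      chains <- perturbation$chains %||% s$chains$chain_id
      idx <- s$atoms$chain_id %in% chains
      s$atoms$x[idx] <- s$atoms$x[idx] + d * dir[1]
      s$atoms$y[idx] <- s$atoms$y[idx] + d * dir[2]
      s$atoms$z[idx] <- s$atoms$z[idx] + d * dir[3]
      s
    },
    per_atom_noise = {
      sig <- perturbation$sigma %||% 0.3
      with_seed(perturbation$seed %||% 1L, {
        n <- nrow(s$atoms)
        s$atoms$x <- s$atoms$x + stats::rnorm(n, 0, sig)
        s$atoms$y <- s$atoms$y + stats::rnorm(n, 0, sig)
        s$atoms$z <- s$atoms$z + stats::rnorm(n, 0, sig)
      })
      s
    },
    uniform_displacement = {
      # displace every residue by exactly d along directions chosen so the
      # net translation and the cross-covariance with the reference CA
      # coordinates vanish: the optimal superposition then stays at the
      # identity and every backbone deviation equals d
      d <- perturbation$d %||% 2
      a <- s$atoms
      poly <- polymer_chain_ids(s)
      ca <- a[a$chain_id %in% poly & a$atom == "CA", ]
      u <- displacement_field(as.matrix(ca[, c("x", "y", "z")]),
                              seed = perturbation$seed %||% 1L)
      rk <- paste(ca$chain_id, ca$resno)
      ak <- paste(a$chain_id, a$resno)
      idx <- match(ak, rk)
      sel <- !is.na(idx) & a$chain_id %in% poly
      s$atoms$x[sel] <- a$x[sel] + d * u[idx[sel], 1]
      s$atoms$y[sel] <- a$y[sel] + d * u[idx[sel], 2]
      s$atoms$z[sel] <- a$z[sel] + d * u[idx[sel], 3]
      s
    },
    drop_chain = {
      k <- perturbation$k %||% 1L
      pc <- polymer_chain_ids(s)
      drop_chains(s, utils::tail(pc, k))
    },
    drop_ligand = {
      k <- perturbation$k %||% 1L
      lc <- ligand_chain_ids(s)
      if (!length(lc)) stop("no ligand chain to drop")
      drop_chains(s, utils::tail(lc, k))
    },
    swap_chain_labels = {
      ent <- s$chains$entity_ref[s$chains$kind != "ligand"]
      dup <- names(which(table(ent) >= 2))[1]
      if (is.na(dup)) stop("no entity with multiple copies to swap")
      ids <- s$chains$chain_id[s$chains$entity_ref == dup &
                                 s$chains$kind != "ligand"][1:2]
      a <- s$atoms$chain_id
      s$atoms$chain_id[a == ids[1]] <- "\r"
      s$atoms$chain_id[a == ids[2]] <- ids[1]
      s$atoms$chain_id[s$atoms$chain_id == "\r"] <- ids[2]
      ord <- order(match(s$atoms$chain_id, s$chains$chain_id), s$atoms$resno)
      s$atoms <- s$atoms[ord, ]
      rownames(s$atoms) <- NULL
      s
    },
    stop("unknown perturbation type '", type, "'"))
}

## ------------------------------------------------------------------------
## Classification battery

rand_seq <- function(n) paste(sample(.amino3, n, replace = TRUE),
                              collapse = "")

#' Generate a classification rule battery
#'
#' Emits targets, a template hit list, template ligand sets, and expected
#' labels spanning every rule branch: identity just above/below the 85%
#' cut, coverage at the 70% bound, 44/45/46 uncovered residues on
#' 300-residue targets, the 250-residue length switch, the 1e-4 e-value
#' cut, peptide exact-match cases, complexes with and without an
#' all-covering template, and ligand-set matches and mismatches. Expected
#' labels come from an independent literal transcription of the rules
#' ([expected_label_literal()]), not from the classification code path.
#'
#' @param seed integer seed.
#' @param n_targets minimum number of targets (>= the 28 fixed boundary
#'   scenarios; extra randomized scenarios are appended).
#' @return list with `targets`, `hits`, `template_ligand_sets`,
#'   `expected` (data.frame target_id, final), `target_lengths`.
#' @export
make_classification_set <- function(seed = 1L, n_targets = 48L) {
  with_seed(seed, {
    targets <- list(); hits <- list(); tls <- list()
    tl <- integer(); tl_names <- character()
    protein_entity <- function(len) {
      s <- rand_seq(len)
      unname(.amino1to3[strsplit(s, "")[[1]]])
    }
    add_target <- function(id, entity_specs, ligand_comps = character(),
                           hit_rows = list(), template_ligands = list()) {
      polys <- lapply(seq_along(entity_specs), function(i) {
        es <- entity_specs[[i]]
        polymer_entity(paste0("e", i), protein_entity(es$len))
      })
      nps <- lapply(seq_along(ligand_comps), function(i)
        nonpolymer_entity(paste0("n", i), ligand_comps[i], "CCO"))
      targets[[length(targets) + 1L]] <<- target_complex(id, polys, nps)
      for (i in seq_along(entity_specs)) {
        key <- paste0(id, ":e", i)
        tl <<- c(tl, entity_specs[[i]]$len); tl_names <<- c(tl_names, key)
      }
      for (h in hit_rows) {
        key <- paste0(id, ":e", h$entity)
        len <- entity_specs[[h$entity]]$len
        covered <- len - h$uncovered
        hits[[length(hits) + 1L]] <<- template_hit(
          key, h$template, identity = h$identity,
          coverage = 100 * covered / len, uncovered = h$uncovered,
          evalue = h$evalue %||% 1e-30, target_length = len)
      }
      for (nm in names(template_ligands))
        tls[[nm]] <<- template_ligands[[nm]]
    }
    pe <- function(len = 120L) list(len = len)
    H <- function(entity, template, identity, uncovered, evalue = 1e-30)
      list(entity = entity, template = template, identity = identity,
           uncovered = uncovered, evalue = evalue)
    uncov <- function(len, coverage_pct) as.integer(round(len * (1 - coverage_pct / 100)))

    # -- single-entity boundary scenarios ---------------------------------
    add_target("T001", list(pe(200)), hit_rows = list(
      H(1, "tpl1", 85.0, uncov(200, 70))))                    # easy boundary
    add_target("T002", list(pe(200)), hit_rows = list(
      H(1, "tpl1", 84.9, uncov(200, 70), evalue = 1e-5)))     # medium: id below cut
    add_target("T003", list(pe(200)), hit_rows = list(
      H(1, "tpl1", 90.0, uncov(200, 69.5))))                  # hard: coverage below 70
    add_target("T004", list(pe(300)), hit_rows = list(
      H(1, "tpl1", 90.0, 44)))                                # easy: 44 uncovered
    add_target("T005", list(pe(300)), hit_rows = list(
      H(1, "tpl1", 90.0, 45)))                                # hard: 45 uncovered fails
    add_target("T006", list(pe(300)), hit_rows = list(
      H(1, "tpl1", 90.0, 46)))                                # hard: 46 uncovered
    add_target("T007", list(pe(250)), hit_rows = list(
      H(1, "tpl1", 90.0, 60)))                                # easy: 250 uses 70% rule only
    add_target("T008", list(pe(251)), hit_rows = list(
      H(1, "tpl1", 90.0, 60)))                                # hard: 251 triggers 45 rule
    add_target("T009", list(pe(200)), hit_rows = list(
      H(1, "tpl1", 60.0, uncov(200, 80), evalue = 1e-4)))     # medium boundary e-value
    add_target("T010", list(pe(200)), hit_rows = list(
      H(1, "tpl1", 60.0, uncov(200, 80), evalue = 2e-4)))     # hard: e-value too large
    add_target("T011", list(pe(200)), hit_rows = list(
      H(1, "tpl1", 60.0, uncov(200, 60), evalue = 1e-9)))     # hard: medium needs coverage
    add_target("T012", list(pe(200)))                         # hard: no hit at all
    add_target("T013", list(pe(12)), hit_rows = list(
      H(1, "tpl1", 100.0, 0)))                                # peptide easy: exact full
    add_target("T014", list(pe(12)), hit_rows = list(
      H(1, "tpl1", 100.0, 1)))                                # peptide hard: coverage < 100
    add_target("T015", list(pe(12)), hit_rows = list(
      H(1, "tpl1", 91.7, 0)))                                 # peptide hard: identity < 100

    # -- complex aggregation ----------------------------------------------
    add_target("T016", list(pe(), pe()), hit_rows = list(
      H(1, "tplA", 95, 0), H(2, "tplA", 95, 0)))              # easy: one all-easy template
    add_target("T017", list(pe(), pe()), hit_rows = list(
      H(1, "tplA", 95, 0), H(2, "tplB", 95, 0)))              # hard: no template covers both
    add_target("T018", list(pe(), pe()), hit_rows = list(
      H(1, "tplA", 95, 0), H(2, "tplA", 60, 0, 1e-9)))        # medium: easy+medium template
    add_target("T019", list(pe(), pe()), hit_rows = list(
      H(1, "tplA", 95, 0), H(2, "tplA", 60, 0, 1),
      H(2, "tplB", 95, 0)))                                   # hard: tplA e2 hard, tplB misses e1
    add_target("T020", list(pe(), pe()), hit_rows = list(
      H(1, "tplA", 60, 0, 1e-9), H(2, "tplA", 55, 0, 1e-9)))  # medium: all-medium template
    add_target("T021", list(pe(), pe(), pe()), hit_rows = list(
      H(1, "tplA", 95, 0), H(2, "tplA", 95, 0), H(3, "tplA", 95, 0),
      H(1, "tplB", 95, 0), H(2, "tplB", 60, 0, 1e-9)))        # easy despite weaker tplB
    add_target("T022", list(pe(), pe()), hit_rows = list(
      H(1, "tplA", 95, 0), H(2, "tplA", 95, 0),
      H(1, "tplB", 95, 0), H(2, "tplB", 95, 0)))              # easy with two easy templates

    # -- ligand-target detection ------------------------------------------
    add_target("T023", list(pe()), ligand_comps = "ATP", hit_rows = list(
      H(1, "tplL1", 95, 0)),
      template_ligands = list(tplL1 = "ATP"))                 # easy: same ligand set
    add_target("T024", list(pe()), ligand_comps = "GTP", hit_rows = list(
      H(1, "tplL2", 95, 0)),
      template_ligands = list(tplL2 = "ATP"))                 # ligand: set mismatch
    add_target("T025", list(pe()), ligand_comps = "ATP", hit_rows = list(
      H(1, "tplL3", 95, 0)),
      template_ligands = list(tplL3 = character()))           # ligand: template empty
    add_target("T026", list(pe()), hit_rows = list(
      H(1, "tplL4", 95, 0)),
      template_ligands = list(tplL4 = character()))           # easy: both empty
    add_target("T027", list(pe()), ligand_comps = c("ATP", "MG"),
      hit_rows = list(H(1, "tplL5", 95, 0), H(1, "tplL6", 95, 0)),
      template_ligands = list(tplL5 = c("MG", "ATP"),
                              tplL6 = "ATP"))                 # easy: one template matches
    add_target("T028", list(pe()), ligand_comps = "ATP", hit_rows = list(
      H(1, "tplL7", 95, 0)),
      template_ligands = list(tplL7 = c("ATP", "HOH")))       # easy: water excluded

    # -- randomized fill to n_targets -------------------------------------
    k <- length(targets)
    while (length(targets) < n_targets) {
      k <- k + 1L
      id <- sprintf("T%03d", k)
      branch <- sample(c("easy", "medium", "hard_cov", "hard_eval"), 1)
      len <- sample(c(80L, 150L, 220L, 300L), 1)
      idn <- switch(branch, easy = stats::runif(1, 86, 99.5),
                    medium = stats::runif(1, 35, 80),
                    hard_cov = stats::runif(1, 86, 99.5),
                    hard_eval = stats::runif(1, 35, 80))
      covp <- switch(branch, easy = stats::runif(1, 85, 100),
                     medium = stats::runif(1, 85, 100),
                     hard_cov = stats::runif(1, 20, 60),
                     hard_eval = stats::runif(1, 85, 100))
      ev <- switch(branch, easy = 1e-20, medium = 1e-10, hard_cov = 1e-20,
                   hard_eval = stats::runif(1, 0.01, 5))
      un <- uncov(len, covp)
      # keep the randomized cases away from the 45-residue knife edge
      if (len > 250 && un %in% 44:46) un <- un + 3L
      add_target(id, list(pe(len)), hit_rows = list(
        H(1, paste0("tplR", k), idn, un, ev)))
    }

    expected <- do.call(rbind, lapply(targets, function(t)
      data.frame(target_id = t$target_id,
                 final = expected_label_literal(t, hits, tls),
                 stringsAsFactors = FALSE)))
    list(targets = targets, hits = hits, template_ligand_sets = tls,
         expected = expected,
         target_lengths = stats::setNames(tl, tl_names))
  })
}

#' Literal transcription of the difficulty rules (test oracle)
#'
#' A direct, self-contained restatement of the labelling rules used to
#' produce expected labels for the classification battery. Intentionally
#' independent of [label_sequence()] / [label_complex()] /
#' [detect_ligand_target()].
#'
#' @param target a [target_complex()].
#' @param hits list of [template_hit()] records (entity keys
#'   `"<target_id>:<entity_id>"`).
#' @param template_ligand_sets named list template_id -> component IDs.
#' @return the expected final label string.
#' @export
expected_label_literal <- function(target, hits, template_ligand_sets) {
  entities <- vapply(target$polymers, function(p) p$entity_id, "")
  kinds <- vapply(target$polymers, function(p) p$kind, "")
  keys <- paste0(target$target_id, ":", entities)
  templates <- unique(vapply(hits, function(h) h$template_id, "")[
    vapply(hits, function(h) h$target_entity, "") %in% keys])
  one <- function(h, kind) {
    if (kind %in% c("peptide", "dna", "rna")) {
      if (h$identity >= 100 - 1e-9 && h$uncovered == 0) return("easy")
      return("hard")
    }
    covered_frac <- (h$target_length - h$uncovered) / h$target_length
    cov_ok <- covered_frac >= 0.70 - 1e-12
    if (h$target_length > 250) cov_ok <- cov_ok && (h$uncovered < 45)
    if (h$identity >= 85 - 1e-9 && cov_ok) return("easy")
    if (h$identity < 85 - 1e-9 && !is.na(h$evalue) && h$evalue <= 1e-4 &&
        cov_ok) return("medium")
    "hard"
  }
  easy_templates <- character(); medium_ok <- FALSE
  for (tpl in templates) {
    labs <- character()
    for (i in seq_along(entities)) {
      hh <- Filter(function(h) h$target_entity == keys[i] &&
                     h$template_id == tpl, hits)
      labs[i] <- if (!length(hh)) "hard" else {
        ll <- vapply(hh, one, "", kind = kinds[i])
        if ("easy" %in% ll) "easy" else if ("medium" %in% ll) "medium" else "hard"
      }
    }
    if (all(labs == "easy")) easy_templates <- c(easy_templates, tpl)
    if (all(labs %in% c("easy", "medium"))) medium_ok <- TRUE
  }
  if (length(easy_templates)) {
    tset <- sort(setdiff(vapply(target$nonpolymers,
                                function(np) np$component_id, ""), "HOH"))
    for (tpl in easy_templates) {
      ts <- sort(setdiff(template_ligand_sets[[tpl]] %||% character(), "HOH"))
      if (identical(ts, tset)) return("easy")
    }
    return("ligand")
  }
  if (medium_ok) return("medium")
  "hard"
}

#' Write a hit list as a 12-column tabular file
#'
#' @param hits list of [template_hit()] records.
#' @param path output path for the hit table.
#' @param lengths_path optional output path for the target-length sidecar
#'   (TSV: id, length).
#' @param target_lengths named lengths used for the sidecar and to recover
#'   qend from coverage.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, lengths_path = NULL,
                            target_lengths = NULL) {
  rows <- vapply(hits, function(h) {
    covered <- h$target_length - h$uncovered
    sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
            h$target_entity, h$template_id, h$identity, covered,
            as.integer(round(covered * (1 - h$identity / 100))), 0L,
            1L, covered, 1L, covered,
            if (is.na(h$evalue)) 0 else h$evalue, 50.0)
  }, "")
  writeLines(rows, path)
  if (!is.null(lengths_path)) {
    stopifnot(!is.null(target_lengths))
    writeLines(paste(names(target_lengths), target_lengths, sep = "\t"),
               lengths_path)
  }
  invisible(path)
}
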