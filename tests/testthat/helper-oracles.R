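# Independent oracles and small builders used across the suite. These are
# deliberately naive re-derivations (nested loops, backtracking search),
# kept separate from the package's code paths.

# Naive all-pairs LDDT: double loop over reference atoms, no vectorised
# distance machinery shared with the implementation.
naive_lddt <- function(model, reference, mapping, inclusion_radius = 15,
                       thresholds = c(0.5, 1, 2, 4), inter_only = FALSE) {
  pc_ref <- reference$chains$chain_id[reference$chains$kind != "ligand"]
  pc_mod <- model$chains$chain_id[model$chains$kind != "ligand"]
  ra <- reference$atoms[reference$atoms$chain_id %in% pc_ref &
                          reference$atoms$element != "H", ]
  ma <- model$atoms[model$atoms$chain_id %in% pc_mod &
                      model$atoms$element != "H", ]
  r2m <- stats::setNames(mapping$pairs$model, mapping$pairs$reference)
  mkey <- paste(ma$chain_id, ma$resno, ma$atom)
  total <- 0; count <- 0L
  for (i in seq_len(nrow(ra))) {
    if (i == nrow(ra)) break
    js <- (i + 1L):nrow(ra)
    dx <- ra$x[js] - ra$x[i]; dy <- ra$y[js] - ra$y[i]; dz <- ra$z[js] - ra$z[i]
    dr <- sqrt(dx^2 + dy^2 + dz^2)
    for (k in seq_along(js)) {
      j <- js[k]
      if (ra$chain_id[i] == ra$chain_id[j] && ra$resno[i] == ra$resno[j]) next
      if (inter_only && ra$chain_id[i] == ra$chain_id[j]) next
      if (dr[k] > inclusion_radius) next
      count <- count + 1L
      mi <- match(paste(r2m[ra$chain_id[i]], ra$resno[i], ra$atom[i]), mkey)
      mj <- match(paste(r2m[ra$chain_id[j]], ra$resno[j], ra$atom[j]), mkey)
      if (is.na(mi) || is.na(mj)) next
      dm <- sqrt((ma$x[mi] - ma$x[mj])^2 + (ma$y[mi] - ma$y[mj])^2 +
                   (ma$z[mi] - ma$z[mj])^2)
      total <- total + mean(abs(dm - dr[k]) <= thresholds)
    }
  }
  if (count == 0L) NA_real_ else total / count
}

# Brute-force automorphism enumeration: backtracking over all candidate
# vertex maps with element and adjacency consistency checks.
brute_force_automorphisms <- function(graph) {
  n <- length(graph$elements)
  adj <- matrix(FALSE, n, n)
  if (nrow(graph$bonds))
    for (r in seq_len(nrow(graph$bonds))) {
      adj[graph$bonds[r, 1], graph$bonds[r, 2]] <- TRUE
      adj[graph$bonds[r, 2], graph$bonds[r, 1]] <- TRUE
    }
  deg <- rowSums(adj)
  found <- list()
  assign_v <- integer(n)
  used <- logical(n)
  recurse <- function(i) {
    if (i > n) {
      found[[length(found) + 1L]] <<- assign_v
      return(invisible())
    }
    for (j in seq_len(n)) {
      if (used[j] || graph$elements[j] != graph$elements[i] ||
          deg[j] != deg[i]) next
      ok <- TRUE
      for (k in seq_len(i - 1L))
        if (adj[i, k] != adj[j, assign_v[k]]) { ok <- FALSE; break }
      if (!ok) next
      assign_v[i] <<- j; used[j] <<- TRUE
      recurse(i + 1L)
      used[j] <<- FALSE
    }
  }
  recurse(1L)
  found
}

# Hand-built structure: one atom (CA) per residue at the given coordinates.
point_chain_structure <- function(id, xyz, chain_id = "A",
                                  comp_id = "GLY") {
  atoms <- data.frame(chain_id = chain_id, resno = seq_len(nrow(xyz)),
                      comp_id = comp_id, atom = "CA", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      is_hetero = FALSE, stringsAsFactors = FALSE)
  eval_structure(id, atoms,
                 data.frame(chain_id = chain_id, entity_ref = "p1",
                            kind = "protein", stringsAsFactors = FALSE))
}

# Random small fixture spec drawn under the current RNG state.
random_small_spec <- function(seed) {
  fixture_spec(seed = seed,
               n_entities = sample(1:2, 1),
               copies_per_entity = sample(1:2, 2, replace = TRUE),
               chain_length = sample(8:14, 1))
}

# Random perturbed model for a reference drawn under the current RNG
# state; chain dropping only on multi-chain references.
random_perturbation <- function(reference = NULL) {
  p <- switch(sample(4, 1),
              list(type = "none"),
              list(type = "per_atom_noise", sigma = stats::runif(1, 0.1, 1.5),
                   seed = sample(1e6, 1)),
              list(type = "rigid_shift", d = stats::runif(1, 1, 8),
                   chains = NULL),
              list(type = "drop_chain", k = 1L))
  if (p$type == "drop_chain" && !is.null(reference) &&
      sum(reference$chains$kind != "ligand") < 2)
    p <- list(type = "none")
  p
}

# Apply a rigid transform (random rotation + translation) to a structure.
rigid_transform <- function(s, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  tr <- stats::rnorm(3, 0, 10)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% q
  s$atoms$x <- xyz[, 1] + tr[1]
  s$atoms$y <- xyz[, 2] + tr[2]
  s$atoms$z <- xyz[, 3] + tr[3]
  s
}
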