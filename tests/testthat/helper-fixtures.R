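# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# random charged residue with a standard backbone and ns side-chain atoms
make_random_residue <- function(ns = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bb_names <- backbone_atom_names()
  sc_names <- paste0("S", seq_len(ns))
  atoms <- data.frame(
    atom_name = c(bb_names, sc_names),
    residue_id = 1L,
    residue_name = "XXX",
    charge = round(stats::runif(length(bb_names) + ns, -1, 1), 4),
    is_backbone = c(rep(TRUE, length(bb_names)), rep(FALSE, ns)),
    stringsAsFactors = FALSE
  )
  nb <- round(stats::runif(length(bb_names), -0.5, 0.5), 4)
  names(nb) <- bb_names
  residue_topology(atoms, neutral_backbone = nb)
}

# residue with prescribed neutral-backbone sum and side-chain charges
make_residue <- function(backbone_neutral, side_charges) {
  nb <- backbone_neutral
  names(nb) <- paste0("B", seq_along(nb))
  atoms <- data.frame(
    atom_name = c(names(nb), paste0("S", seq_along(side_charges))),
    residue_id = 1L, residue_name = "XXX",
    charge = c(rep(0, length(nb)), side_charges),
    is_backbone = c(rep(TRUE, length(nb)),
                    rep(FALSE, length(side_charges))),
    stringsAsFactors = FALSE
  )
  residue_topology(atoms, neutral_backbone = nb)
}

# toy protein-like structure with charged residues at given centers
make_structure <- function(id, jitter = 0, seed = 1) {
  set.seed(seed)
  res <- list(
    list(name = "HIS", id = 64L,
         atoms = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
         base = c(0, 0, 0)),
    list(name = "LYS", id = 94L, atoms = c("CB", "NZ"),
         base = c(8, 0, 0)),
    list(name = "ASP", id = 60L, atoms = c("CB", "CG"),
         base = c(0, 9, 0)),
    list(name = "GLU", id = 12L, atoms = c("CB", "CD"),
         base = c(-7, -5, 3))
  )
  atoms <- do.call(rbind, lapply(res, function(r) {
    n <- length(r$atoms)
    k <- seq_len(n)
    offs <- cbind(sin(k), cos(k), sin(2 * k + 1)) * 0.8
    data.frame(atom_name = r$atoms, residue_id = r$id,
               residue_name = r$name,
               x = r$base[1] + offs[, 1] + stats::rnorm(n, 0, jitter),
               y = r$base[2] + offs[, 2] + stats::rnorm(n, 0, jitter),
               z = r$base[3] + offs[, 3] + stats::rnorm(n, 0, jitter),
               stringsAsFactors = FALSE)
  }))
  anchor <- which(atoms$residue_id == 64L)
  structure_entry(id, atoms, anchor)
}

# apply a rigid motion to a structure_entry
transform_structure <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[c("x", "y", "z")]) %*% R
  xyz <- sweep(xyz, 2, t, `+`)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# toy aligned FASTA written to a temp file; returns the path
write_toy_alignment <- function(seqs, path = tempfile(fileext = ".fasta")) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  close(con)
  path
}

# canonical double-well study system for sampler tests
reference_double_well <- function(q = 0) double_well(barrier = 10, q = q)

reference_windows <- list(RS = c(-1.6, -0.4), TS = c(-0.4, 0.4),
                          PS = c(0.4, 1.6))

reference_grid <- seq(-1.8, 1.8, length.out = 200)
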