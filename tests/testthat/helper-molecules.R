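# Shared molecule preparation, cached so the RDKit helper runs once per
# test session. Template: DMP (the highest-composite-index PAE).

.pae_cache <- new.env(parent = emptyenv())

pae_prepared <- function() {
  if (is.null(.pae_cache$mols)) {
    smi <- load_fixture("pae_smiles")
    mols <- paedesign:::.prepare_molecules(smi$smiles, smi$compound,
                                           seed = 20220309, minimize = TRUE)
    .pae_cache$mols <- lapply(mols, assign_atom_parameters)
  }
  .pae_cache$mols
}

pae_aligned <- function() {
  if (is.null(.pae_cache$aligned)) {
    mols <- pae_prepared()
    tpl <- mols[["DMP"]]
    .pae_cache$aligned <- lapply(mols, function(m)
      align_to_template(m, tpl)$mol)
  }
  .pae_cache$aligned
}

pae_block <- function() {
  if (is.null(.pae_cache$block)) {
    amols <- pae_aligned()
    grid <- build_grid(amols, margin = 2, spacing = 2)
    .pae_cache$block <- assemble_descriptors(amols, grid)
  }
  .pae_cache$block
}

# a tiny hand-built point-set molecule for field arithmetic tests
point_molecule <- function(xyz, radius = 1.7, charge = 0, logp = 0,
                           donor = 0, acceptor = 0, elem = "C",
                           name = "pt") {
  n <- nrow(xyz)
  atoms <- data.frame(
    elem = rep(elem, length.out = n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    formal = 0,
    charge = rep(charge, length.out = n),
    logp_inc = rep(logp, length.out = n),
    aromatic = FALSE, n_h = 0,
    radius = rep(radius, length.out = n),
    donor = rep(donor, length.out = n),
    acceptor = rep(acceptor, length.out = n),
    stringsAsFactors = FALSE)
  structure(list(name = name, smiles = NA_character_, atoms = atoms,
                 bonds = data.frame(a1 = integer(0), a2 = integer(0),
                                    order = numeric(0)),
                 meta = list(seed = NA)),
            class = "pae_mol")
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}
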