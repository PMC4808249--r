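# Deterministic synthetic-structure and synthetic-MSA generators. These are
# first-class package code: every pipeline stage can be exercised without
# network access. Backbones are built from ideal internal coordinates (NeRF
# chain extension); hinge pairs emulate an open/closed transition with a
# planted ligand; MSAs plant conserved columns and optional sequence
# families.

# ideal backbone internal coordinates (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place atom D from A-B-C with bond |CD|, angle B-C-D and torsion A-B-C-D
.nerf_place <- function(A, B, C, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  bc <- C - B; bc <- bc / .vnorm(bc)
  ab <- B - A; ab <- ab / .vnorm(ab)
  nv <- .cross3(ab, bc); nv <- nv / .vnorm(nv)
  m2 <- .cross3(nv, bc)
  M <- cbind(bc, m2, nv)
  as.numeric(C + M %*% d2)
}

.rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / .vnorm(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.random_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(names(KYTE_DOOLITTLE), n, replace = TRUE), collapse = "")
}

.backbone_coords <- function(n, phi, psi, omega = 180) {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  N <- CA <- C <- O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
      CA[i, ] <- .nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                             BOND_N_CA, ANGLE_C_N_CA, omega)
      C[i, ] <- .nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                            BOND_CA_C, ANGLE_N_CA_C, phi[i])
    }
    O[i, ] <- .nerf_place(N[i, ], CA[i, ], C[i, ],
                          BOND_C_O, ANGLE_CA_C_O, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

.residues_from_coords <- function(coords, sequence, chain, numbers = NULL) {
  n <- nrow(coords$CA)
  letters1 <- strsplit(sequence, "")[[1]]
  numbers <- numbers %||% seq_len(n)
  lapply(seq_len(n), function(i) {
    n3 <- AA_ONE_TO_THREE[letters1[i]]
    atoms <- list(new_atom("N", "N", coords$N[i, ]),
                  new_atom("CA", "C", coords$CA[i, ]),
                  new_atom("C", "C", coords$C[i, ]),
                  new_atom("O", "O", coords$O[i, ]))
    new_residue(unname(n3), chain, numbers[i], atoms = atoms)
  })
}

.structure_file_of <- function(id, chain, seqres1, residues, hets = list(),
                               resolution = 1.8) {
  s3 <- unname(AA_ONE_TO_THREE[strsplit(seqres1, "")[[1]]])
  ps <- map_observed_to_seqres(list(chain_id = chain, seqres3 = s3,
                                    observed = residues), file_id = id)
  het_groups <- if (length(hets)) {
    data.frame(comp_id = vapply(hets, function(r) r$name3, character(1)),
               n_atoms = vapply(hets, function(r) length(r$atoms), integer(1)),
               stringsAsFactors = FALSE)
  } else data.frame(comp_id = character(0), n_atoms = integer(0))
  structure(list(id = id, protein_chains = stats::setNames(list(ps), chain),
                 nucleic_chains = list(), het_residues = hets,
                 het_groups = het_groups, waters = 0L,
                 metadata = list(resolution = resolution, ph = 7.0,
                                 temperature = 100)),
            class = "structure_file")
}

#' Generate an ideal synthetic backbone
#'
#' Builds a full-backbone (N, CA, C, O) chain from ideal bond lengths and
#' angles at the requested torsions: an alpha-helix (phi = -57, psi = -47),
#' an extended chain (phi = -139, psi = 135) or custom angles. Deterministic
#' for a fixed seed.
#'
#' @param length number of residues (>= 4).
#' @param geometry `"helix"`, `"extended"` or `"custom"`.
#' @param phi,psi torsions in degrees (used when `geometry = "custom"`).
#' @param sequence amino-acid string; random (seeded) when NULL.
#' @param chain,id chain and file ids.
#' @param delete SEQRES indices whose coordinates are removed (disordered).
#' @param seed RNG seed for the random sequence.
#' @return a `structure_file` with one protein chain.
#' @export
make_backbone <- function(length, geometry = c("helix", "extended", "custom"),
                          phi = -57, psi = -47, sequence = NULL, chain = "A",
                          id = "SYN1", delete = integer(0), seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(length >= 4)
  if (geometry == "helix") { phi <- -57; psi <- -47 }
  if (geometry == "extended") { phi <- -139; psi <- 135 }
  sequence <- sequence %||% .random_sequence(length, seed)
  stopifnot(nchar(sequence) == length)
  coords <- .backbone_coords(length, phi, psi)
  res <- .residues_from_coords(coords, sequence, chain)
  keep <- setdiff(seq_len(length), delete)
  .structure_file_of(id, chain, sequence, res[keep])
}

#' Place a small het group near a residue
#'
#' A rigid three-heavy-atom group positioned on the outward ray through the
#' anchor residue's CA so that the minimum heavy-atom distance between the
#' group and the anchor residue is exactly `distance` (to 1e-6 Angstrom, by
#' bisection along the ray). The outward placement keeps other residues at
#' least as far away in practice.
#'
#' @param sf a `structure_file` (single chain).
#' @param comp_id component id for the group.
#' @param anchor SEQRES index of the anchored residue.
#' @param distance minimum group-to-anchor heavy-atom distance in Angstrom.
#' @return the `structure_file` with the het group added.
#' @export
plant_ligand <- function(sf, comp_id, anchor, distance = 4.0) {
  ps <- sf$protein_chains[[1]]
  ca <- ca_matrix(ps)
  # radial direction away from the local backbone axis, so the group clears
  # the anchor's neighbours as well
  nbr <- intersect((anchor - 4L):(anchor + 4L), ps$observed_idx)
  dir <- ca[anchor, ] - colMeans(ca[nbr, , drop = FALSE])
  if (.vnorm(dir) < 1e-6) {
    dir <- ca[anchor, ] - colMeans(ca[ps$observed_idx, , drop = FALSE])
  }
  dir <- dir / .vnorm(dir)
  perp <- .cross3(dir, c(0, 0, 1))
  if (.vnorm(perp) < 1e-6) perp <- .cross3(dir, c(0, 1, 0))
  perp <- perp / .vnorm(perp)

  anchor_res <- ps$observed[[anchor]]
  chain_coords <- do.call(rbind, lapply(heavy_atoms(anchor_res),
                                        function(a) a$coords))
  group_at <- function(t) {
    base <- ca[anchor, ] + t * dir
    rbind(base, base + 1.4 * dir, base + 1.0 * dir + 1.0 * perp)
  }
  min_dist <- function(t) {
    g <- group_at(t)
    d2 <- outer(rowSums(g^2), rowSums(chain_coords^2), "+") -
      2 * g %*% t(chain_coords)
    sqrt(max(0, min(d2)))
  }
  lo <- 0; hi <- distance + 20
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (min_dist(mid) < distance) lo <- mid else hi <- mid
  }
  g <- group_at(hi)
  atoms <- list(new_atom("C1", "C", g[1, ]),
                new_atom("O1", "O", g[2, ]),
                new_atom("N1", "N", g[3, ]))
  het <- new_residue(comp_id, "L", 1L, atoms = atoms, is_het = TRUE)
  sf$het_residues <- c(sf$het_residues, list(het))
  sf$het_groups <- rbind(sf$het_groups,
                         data.frame(comp_id = comp_id,
                                    n_atoms = length(atoms),
                                    stringsAsFactors = FALSE))
  sf
}

#' Generate a free/bound hinge pair
#'
#' The free structure is an ideal backbone; the bound copy has every residue
#' past the hinge rotated by `angle` degrees about an axis through the hinge
#' CA, plus a planted ligand, so the two files satisfy the pairing
#' conditions (same SEQRES, bound file holds one extra molecule).
#'
#' @param length chain length (default 60).
#' @param hinge hinge residue (default 30).
#' @param angle hinge rotation in degrees.
#' @param geometry backbone geometry, see [make_backbone()].
#' @param ligand list(`comp_id`, `anchor`, `distance`) or NULL; a NULL
#'   `anchor` defaults to three quarters of the way along the chain.
#' @param delete_free,delete_bound SEQRES indices without coordinates in the
#'   respective copy.
#' @param seed RNG seed (sequence).
#' @param ids the two file ids.
#' @return list(`free`, `bound`) of `structure_file`s.
#' @export
make_hinge_pair <- function(length = 60, hinge = 30, angle = 30,
                            geometry = "helix",
                            ligand = list(comp_id = "GNP", anchor = NULL,
                                          distance = 4.0),
                            delete_free = integer(0),
                            delete_bound = integer(0),
                            seed = 1, ids = c("SYNF", "SYNB")) {
  stopifnot(hinge > 1, hinge < length)
  sequence <- .random_sequence(length, seed)
  coords <- .backbone_coords(
    length,
    phi = if (geometry == "helix") -57 else -139,
    psi = if (geometry == "helix") -47 else 135)

  res_free <- .residues_from_coords(coords, sequence, "A")
  keepf <- setdiff(seq_len(length), delete_free)
  free <- .structure_file_of(ids[1], "A", sequence, res_free[keepf])

  R <- .rotation_about_axis(c(0, 0, 1), angle)
  pivot <- coords$CA[hinge, ]
  moved <- coords
  for (nm in names(moved)) {
    for (i in (hinge + 1L):length) {
      moved[[nm]][i, ] <- as.numeric(R %*% (coords[[nm]][i, ] - pivot)) + pivot
    }
  }
  res_bound <- .residues_from_coords(moved, sequence, "A")
  keepb <- setdiff(seq_len(length), delete_bound)
  bound <- .structure_file_of(ids[2], "A", sequence, res_bound[keepb])
  if (!is.null(ligand)) {
    anchor <- ligand$anchor %||% ceiling(0.75 * length)
    bound <- plant_ligand(bound, ligand$comp_id, anchor,
                          ligand$distance %||% 4.0)
  }
  list(free = free, bound = bound)
}

#' Generate a synthetic MSA
#'
#' Aligned sequences of length `L`: planted conserved columns carry a single
#' residue type in every row; other columns are sampled uniformly. With
#' `families = 2` the rows split into two groups, each derived from its own
#' consensus with `within_noise` per-column mutation probability, giving high
#' within-family and low between-family identity for independent-count
#' tests. Row 1 is the reference (named `ref`).
#'
#' @param L alignment length.
#' @param n number of rows (>= 1).
#' @param conserved_positions columns forced to a single type.
#' @param families 1 or 2.
#' @param within_noise per-column mutation rate inside a family.
#' @param seed RNG seed.
#' @return an `msa` object (no gaps).
#' @export
make_msa <- function(L, n, conserved_positions = integer(0), families = 1,
                     within_noise = 0.05, seed = 1) {
  stopifnot(n >= 1, families %in% c(1, 2))
  set.seed(seed)
  alphabet <- names(KYTE_DOOLITTLE)
  consensus <- lapply(seq_len(families), function(f)
    sample(alphabet, L, replace = TRUE))
  conserved_letters <- sample(alphabet, max(1, length(conserved_positions)),
                              replace = TRUE)
  rows <- matrix("", n, L)
  fam_of <- if (families == 2) rep(1:2, length.out = n) else rep(1, n)
  for (r in seq_len(n)) {
    base <- consensus[[fam_of[r]]]
    if (families == 1 && r > 1) {
      # unrelated rows: resample everything non-conserved
      base <- sample(alphabet, L, replace = TRUE)
    } else if (r > families) {
      mut <- stats::runif(L) < within_noise
      base[mut] <- sample(alphabet, sum(mut), replace = TRUE)
    }
    rows[r, ] <- base
  }
  for (k in seq_along(conserved_positions)) {
    rows[, conserved_positions[k]] <- conserved_letters[k]
  }
  ids <- c("ref", sprintf("seq%03d", seq_len(max(0, n - 1))))[seq_len(n)]
  ref <- reference_sequence("ref", paste(rows[1, ], collapse = ""))
  msa_from_matrix(rows, ids, ref)
}

#' Write an MSA to aligned FASTA
#' @param msa an `msa` object.
#' @param path output path.
#' @export
write_msa <- function(msa, path) {
  out <- character(0)
  for (r in seq_len(nrow(msa$rows))) {
    out <- c(out, paste0(">", msa$ids[r]),
             paste(msa$rows[r, ], collapse = ""))
  }
  writeLines(out, path)
  invisible(path)
}

#' Generate a two-strand antiparallel sheet
#'
#' One chain whose first `n_strand` residues form an extended strand and
#' whose last `n_strand` residues form the antiparallel partner (rotated 180
#' degrees and translated to hydrogen-bonding register); the linker residues
#' in between stay in SEQRES but carry no coordinates.
#'
#' @param n_strand residues per strand.
#' @param linker disordered linker length.
#' @param separation inter-strand spacing in Angstrom.
#' @param shift registration shift along the strand axis in Angstrom.
#' @param seed RNG seed (sequence).
#' @param id file id.
#' @return a `structure_file`.
#' @export
make_sheet <- function(n_strand = 8, linker = 4, separation = 4.2,
                       shift = -2.5, seed = 2, id = "SYNS") {
  L <- 2L * n_strand + linker
  sequence <- .random_sequence(L, seed)
  c1 <- .backbone_coords(n_strand, phi = -139, psi = 135)
  # canonicalise: principal CA axis along x, pleat plane in xy, so that the
  # partner strand can be placed by a z-rotation plus a y-translation
  ca <- c1$CA
  ctr <- colMeans(ca)
  pcs <- svd(sweep(ca, 2, ctr))$v
  if (pcs[1, 1] < 0) pcs[, 1] <- -pcs[, 1]
  if (det(pcs) < 0) pcs[, 3] <- -pcs[, 3]
  c1 <- lapply(c1, function(m) sweep(m, 2, ctr) %*% pcs)
  # antiparallel partner: 180-degree rotation about z reverses the strand
  # direction while keeping per-residue geometry intact
  R <- .rotation_about_axis(c(0, 0, 1), 180)
  flip <- function(m) {
    t(apply(m, 1, function(v) as.numeric(R %*% v))) +
      matrix(c(shift, separation, 0), nrow(m), 3, byrow = TRUE)
  }
  c2 <- lapply(c1, flip)
  res1 <- .residues_from_coords(c1, substr(sequence, 1, n_strand), "A",
                                numbers = seq_len(n_strand))
  res2 <- .residues_from_coords(c2,
                                substr(sequence, n_strand + linker + 1L, L),
                                "A",
                                numbers = (n_strand + linker + 1L):L)
  .structure_file_of(id, "A", sequence, c(res1, res2))
}
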