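# Idealised residue templates for the chondroitin building blocks. Rings are
# built as 4C1 chairs by internal-coordinate placement (tetrahedral angles,
# alternating +/-60 degree ring torsions, the sign pattern of the D-series),
# then decorated with axial/equatorial substituents. Bond lengths: C-C 1.52,
# C-O 1.43, anomeric C1-O1 1.41, C-N 1.47, amide N-C 1.33, C=O 1.23,
# carboxylate C-O 1.25, O-H 0.96, N-H 1.01, C-H 1.09 angstroms.

BOND_CC <- 1.52
BOND_CO <- 1.43
BOND_ANOMERIC <- 1.41
ANGLE_TET <- 109.47
ANGLE_GLYCOSIDIC <- 117

#' Build an idealised residue template
#'
#' Constructs a single beta-D-pyranose residue in the 4C1 chair conformation
#' with all hydrogens and exocyclic groups placed. `GalNAc`
#' (N-acetyl-D-galactosamine) carries the axial C4 hydroxyl that distinguishes
#' the galacto from the gluco configuration, an N-acetyl group at C2 (trans
#' acetamido by default) and a hydroxymethyl group at C5; `GlcA` (D-glucuronic
#' acid) carries equatorial hydroxyls at C2-C4 and a carboxylate at C5.
#' Atom numbering follows the IUPAC carbohydrate convention (ring atoms
#' O5, C1..C5; hydrogens take the number of the bonded carbon).
#'
#' @param kind `"GalNAc"` or `"GlcA"`.
#' @param anomer Configuration at C1, `"beta"` (equatorial O1, the default) or
#'   `"alpha"` (axial O1). Only meaningful for a reducing-end residue.
#' @return An object of class `glycan_residue`: a list with elements `kind`,
#'   `anomer`, `atoms` (tibble with columns `atom`, `element`, `x`, `y`, `z`)
#'   and `ring_atoms` (the ordered six-tuple O5, C1, C2, C3, C4, C5).
#' @examples
#' tpl <- build_residue_template("GalNAc")
#' ring_pucker_torsions(tpl)
#' @export
build_residue_template <- function(kind, anomer = c("beta", "alpha")) {
  kind <- as.character(kind)
  if (!kind %in% c("GalNAc", "GlcA")) {
    stop("unknown residue kind: '", kind, "' (expected 'GalNAc' or 'GlcA')",
         call. = FALSE)
  }
  anomer <- match.arg(anomer)

  ring <- build_chair_ring()
  pos <- ring$pos # named list O5, C1..C5

  o1_mode <- if (anomer == "beta") "eq" else "ax"
  # substituent plan: per ring carbon, heteroatom/C6 placement and its mode
  plan <- list(
    C1 = list(name = "O1", len = BOND_ANOMERIC, mode = o1_mode),
    C2 = if (kind == "GalNAc") list(name = "N", len = 1.47, mode = "eq")
         else list(name = "O2", len = BOND_CO, mode = "eq"),
    C3 = list(name = "O3", len = BOND_CO, mode = "eq"),
    C4 = list(name = "O4", len = BOND_CO,
              mode = if (kind == "GalNAc") "ax" else "eq"),
    C5 = list(name = "C6", len = BOND_CC, mode = "eq")
  )

  normal <- ring_normal(pos)
  neighbours <- list(
    C1 = c("O5", "C2"), C2 = c("C1", "C3"), C3 = c("C2", "C4"),
    C4 = c("C3", "C5"), C5 = c("C4", "O5")
  )

  for (carbon in names(plan)) {
    p <- plan[[carbon]]
    nb <- neighbours[[carbon]]
    dirs <- tetrahedral_directions(pos[[carbon]], pos[[nb[1]]], pos[[nb[2]]],
                                   normal)
    sub_dir <- if (p$mode == "ax") dirs$axial else dirs$equatorial
    h_dir <- if (p$mode == "ax") dirs$equatorial else dirs$axial
    pos[[p$name]] <- pos[[carbon]] + p$len * sub_dir
    pos[[paste0("H", substring(carbon, 2))]] <- pos[[carbon]] + 1.09 * h_dir
  }

  # second shell ------------------------------------------------------------
  # anomeric hydroxyl (removed on non-reducing residues at assembly time)
  pos$HO1 <- nerf_place(pos$O5, pos$C1, pos$O1, 0.96, 107, 180)
  pos$HO3 <- nerf_place(pos$C2, pos$C3, pos$O3, 0.96, 107, 180)
  pos$HO4 <- nerf_place(pos$C3, pos$C4, pos$O4, 0.96, 107, 180)

  if (kind == "GalNAc") {
    # hydroxymethyl, omega = O5-C5-C6-O6, default trans
    pos$O6 <- nerf_place(pos$O5, pos$C5, pos$C6, BOND_CO, ANGLE_TET, 180)
    pos$H61 <- nerf_place(pos$O5, pos$C5, pos$C6, 1.09, ANGLE_TET, 60)
    pos$H62 <- nerf_place(pos$O5, pos$C5, pos$C6, 1.09, ANGLE_TET, -60)
    pos$HO6 <- nerf_place(pos$C5, pos$C6, pos$O6, 0.96, 107, 180)
    # N-acetyl at C2: planar trans amide, H2-C2-N-HN = 180 by default
    pos$HN <- nerf_place(pos$H2, pos$C2, pos$N, 1.01, 118, 180)
    pos$C7 <- nerf_place(pos$H2, pos$C2, pos$N, 1.33, 123, 0)
    pos$O7 <- nerf_place(pos$C2, pos$N, pos$C7, 1.23, 122, 0)
    pos$C8 <- nerf_place(pos$C2, pos$N, pos$C7, 1.50, 116, 180)
  } else {
    pos$HO2 <- nerf_place(pos$C1, pos$C2, pos$O2, 0.96, 107, 180)
    # carboxylate: sp2 C6, the two oxygens anti about the C5-C6 axis
    pos$O6A <- nerf_place(pos$O5, pos$C5, pos$C6, 1.25, 117, 120)
    pos$O6B <- nerf_place(pos$O5, pos$C5, pos$C6, 1.25, 117, -60)
  }

  atoms <- tibble::tibble(
    atom = names(pos),
    element = element_of(names(pos)),
    x = vapply(pos, `[`, numeric(1), 1),
    y = vapply(pos, `[`, numeric(1), 2),
    z = vapply(pos, `[`, numeric(1), 3)
  )
  if (anyDuplicated(atoms$atom)) {
    stop("internal error: duplicate atom names in template", call. = FALSE)
  }

  structure(
    list(kind = kind, anomer = anomer, atoms = atoms,
         ring_atoms = c("O5", "C1", "C2", "C3", "C4", "C5")),
    class = "glycan_residue"
  )
}

# Chair ring: O5 at the origin, C1 along x, C2 in the xy plane, C3-C5 by NeRF
# with the alternating +/-60 degree torsion pattern of a 4C1 D-pyranose
# (positive O5-C1-C2-C3). The C5-O5 closure bond is emergent.
build_chair_ring <- function() {
  pos <- list()
  pos$O5 <- c(0, 0, 0)
  pos$C1 <- c(BOND_CO, 0, 0)
  th <- ANGLE_TET / DEG
  pos$C2 <- pos$C1 + BOND_CC * c(-cos(th), sin(th), 0)
  pos$C3 <- nerf_place(pos$O5, pos$C1, pos$C2, BOND_CC, ANGLE_TET, 60)
  pos$C4 <- nerf_place(pos$C1, pos$C2, pos$C3, BOND_CC, ANGLE_TET, -60)
  pos$C5 <- nerf_place(pos$C2, pos$C3, pos$C4, BOND_CO, ANGLE_TET, 60)
  list(pos = pos)
}

ring_normal <- function(pos) {
  ring <- rbind(pos$O5, pos$C1, pos$C2, pos$C3, pos$C4, pos$C5)
  ctr <- colMeans(ring)
  n <- c(0, 0, 0)
  for (i in seq_len(6)) {
    j <- if (i == 6) 1 else i + 1
    n <- n + vcross(ring[i, ] - ctr, ring[j, ] - ctr)
  }
  vunit(n)
}

# The two free tetrahedral directions at a ring carbon, classified as axial
# (more parallel to the ring normal) and equatorial.
tetrahedral_directions <- function(center, nb1, nb2, normal) {
  u <- vunit(nb1 - center)
  v <- vunit(nb2 - center)
  w <- -vunit(u + v)
  p <- vunit(vcross(u, v))
  half <- (ANGLE_TET / 2) / DEG
  d1 <- w * cos(half) + p * sin(half)
  d2 <- w * cos(half) - p * sin(half)
  if (abs(sum(d1 * normal)) >= abs(sum(d2 * normal))) {
    list(axial = d1, equatorial = d2)
  } else {
    list(axial = d2, equatorial = d1)
  }
}

element_of <- function(atom) {
  substring(gsub("^([A-Za-z]).*", "\\1", atom), 1, 1)
}

is_heavy <- function(element) element != "H"

#' @export
print.glycan_residue <- function(x, ...) {
  cat("<glycan_residue> ", x$kind, " (", x$anomer, "), ",
      nrow(x$atoms), " atoms\n", sep = "")
  print(x$atoms, n = 5)
  invisible(x)
}

# Ring torsion quadruples in template order; the expected 4C1 sign pattern is
# +60, -60, +60, -60, +60, -60.
ring_quadruples <- function(ring_atoms = c("O5", "C1", "C2", "C3", "C4", "C5")) {
  lapply(seq_len(6), function(i) ring_atoms[((i - 1):(i + 2)) %% 6 + 1])
}

RING_SIGNS <- c(1, -1, 1, -1, 1, -1)
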