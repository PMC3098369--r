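# Chain assembly for chondroitin oligosaccharides. Residues are rigid 4C1
# bodies; the degrees of freedom are the glycosidic (phi, psi) pair of every
# linkage plus the named exocyclic torsions of each GalNAc residue
# (hydroxymethyl omega = O5-C5-C6-O6 and the acetamido H2-C2-N-HN torsion,
# both defaulting to trans). Chains follow the chondroitin repeat: GalNAc at
# the reducing end (residue 1), then alternating GlcA/GalNAc, joined by
# beta(1->3) linkages GlcA -> GalNAc and beta(1->4) linkages GalNAc -> GlcA.

# cache for chain topologies (templates never change)
the <- new.env(parent = emptyenv())

residue_kind_at <- function(i) if (i %% 2 == 1) "GalNAc" else "GlcA"

residue_label_at <- function(i) {
  paste0(if (i %% 2 == 1) "N" else "U", i)
}

# Topology: everything about a chain of given length that does not depend on
# the torsions. Used by assemble_chain() and (heavily) by the annealer.
chain_topology <- function(length, anomer = "beta") {
  key <- paste0("topo_", length, "_", anomer)
  if (!is.null(the[[key]])) return(the[[key]])

  stopifnot(length >= 2)
  n_link <- length - 1
  res <- vector("list", length)
  for (i in seq_len(length)) {
    kind <- residue_kind_at(i)
    tpl <- build_residue_template(kind, if (i == 1) anomer else "beta")
    atoms <- tpl$atoms
    drop <- character(0)
    if (i > 1) drop <- c(drop, "HO1")                    # donor side
    if (i < length) {                                     # acceptor side
      drop <- c(drop, if (kind == "GalNAc") c("O3", "HO3") else c("O4", "HO4"))
    }
    link_o <- if (kind == "GalNAc") "O3" else "O4"
    link_o_local <- as.numeric(atoms[atoms$atom == link_o, c("x", "y", "z")])
    atoms <- atoms[!atoms$atom %in% drop, ]
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    rownames(xyz) <- atoms$atom
    res[[i]] <- list(
      kind = kind, label = residue_label_at(i), atoms = atoms$atom,
      element = atoms$element, xyz = xyz, link_o_local = link_o_local,
      acceptor_atom = if (kind == "GalNAc") "C3" else "C4",
      psi_ref_atom = if (kind == "GalNAc") "C4" else "C5"
    )
  }

  # donor anchor internal geometry (same for every non-reducing residue of a
  # given kind, but measured per template for exactness)
  for (i in seq_len(length)) {
    xyz <- res[[i]]$xyz
    res[[i]]$d_c1_o5 <- vnorm(xyz["C1", ] - xyz["O5", ])
    res[[i]]$ang_o5_c1_o1 <- bond_angle(xyz["O5", ], xyz["C1", ], xyz["O1", ])
  }

  atom_tab <- purrr::map_dfr(seq_len(length), function(i) {
    tibble::tibble(
      residue = i, kind = res[[i]]$kind, label = res[[i]]$label,
      atom = res[[i]]$atoms, element = res[[i]]$element
    )
  })
  atom_tab$index <- seq_len(nrow(atom_tab))
  offsets <- c(0, cumsum(vapply(res, function(r) length(r$atoms), integer(1))))

  # exocyclic rotatable torsions (GalNAc residues only)
  exo <- list()
  for (i in seq_len(length)) {
    if (res[[i]]$kind != "GalNAc") next
    nm <- res[[i]]$atoms
    grp_omega <- intersect(c("O6", "H61", "H62", "HO6"), nm)
    grp_acet <- intersect(c("HN", "C7", "O7", "C8"), nm)
    exo[[res[[i]]$label]] <- list(
      residue = i,
      omega = list(axis = c("C5", "C6"), ref = c("O5", "O6"), group = grp_omega),
      acetamido = list(axis = c("C2", "N"), ref = c("H2", "HN"), group = grp_acet)
    )
  }

  linkages <- tibble::tibble(
    linkage = seq_len(n_link),
    donor = seq_len(n_link) + 1L,
    acceptor = seq_len(n_link),
    type = ifelse(seq_len(n_link) %% 2 == 1, "b13", "b14")
  )
  linkages$donor_label <- vapply(linkages$donor, residue_label_at, character(1))
  linkages$acceptor_label <- vapply(linkages$acceptor, residue_label_at, character(1))

  topo <- list(length = length, anomer = anomer, residues = res,
               atoms = atom_tab, offsets = offsets, exo = exo,
               linkages = linkages)
  topo$steric_pairs <- steric_pair_table(topo)
  the[[key]] <- topo
  topo
}

# Heavy-atom pairs more than three bonds apart and in different residues
# (intra-residue geometry is rigid, so its steric contribution is constant).
steric_pair_table <- function(topo) {
  at <- topo$atoms
  bonds <- list()
  for (i in seq_len(topo$length)) {
    xyz <- topo$residues[[i]]$xyz
    el <- topo$residues[[i]]$element
    n <- nrow(xyz)
    off <- topo$offsets[i]
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        d <- vnorm(xyz[a, ] - xyz[b, ])
        cutoff <- if (el[a] == "H" || el[b] == "H") 1.25 else 1.75
        if (d < cutoff) bonds[[length(bonds) + 1]] <- c(off + a, off + b)
      }
    }
  }
  for (k in seq_len(nrow(topo$linkages))) {
    don <- topo$linkages$donor[k]
    acc <- topo$linkages$acceptor[k]
    o1 <- atom_index(topo, don, "O1")
    cx <- atom_index(topo, acc, topo$residues[[acc]]$acceptor_atom)
    bonds[[length(bonds) + 1]] <- c(o1, cx)
  }
  bm <- do.call(rbind, bonds)
  g <- igraph::graph_from_edgelist(bm, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(at) - igraph::vcount(g)))
  sep <- igraph::distances(g)
  heavy <- which(at$element != "H")
  pairs <- which(upper.tri(sep), arr.ind = TRUE)
  keep <- pairs[, 1] %in% heavy & pairs[, 2] %in% heavy &
    at$residue[pairs[, 1]] != at$residue[pairs[, 2]] &
    sep[pairs] > 3
  pairs[keep, , drop = FALSE]
}

atom_index <- function(topo, residue, atom) {
  off <- topo$offsets[residue]
  hit <- match(atom, topo$residues[[residue]]$atoms)
  if (is.na(hit)) {
    stop("atom '", atom, "' not found in residue ",
         topo$residues[[residue]]$label, call. = FALSE)
  }
  off + hit
}

# Core coordinate builder: torsion parameters in, N x 3 matrix out.
# par: list(phi, psi (length n_link), omega, acetamido (one per GalNAc)).
chain_coords <- function(topo, par) {
  n_res <- topo$length
  coords <- matrix(NA_real_, nrow(topo$atoms), 3)
  transforms <- vector("list", n_res)

  local_xyz <- vector("list", n_res)
  gal_i <- 0
  for (i in seq_len(n_res)) {
    xyz <- topo$residues[[i]]$xyz
    if (topo$residues[[i]]$kind == "GalNAc") {
      gal_i <- gal_i + 1
      ex <- topo$exo[[topo$residues[[i]]$label]]
      xyz <- apply_exo_torsion(xyz, ex$omega, par$omega[gal_i])
      xyz <- apply_exo_torsion(xyz, ex$acetamido, par$acetamido[gal_i])
    }
    local_xyz[[i]] <- xyz
  }

  idx1 <- (topo$offsets[1] + 1):topo$offsets[2]
  coords[idx1, ] <- local_xyz[[1]]
  transforms[[1]] <- list(r = diag(3), shift = c(0, 0, 0))

  for (k in seq_len(n_res - 1)) {
    acc <- k
    don <- k + 1
    acc_res <- topo$residues[[acc]]
    tr <- transforms[[acc]]
    o1_t <- as.vector(tr$r %*% acc_res$link_o_local) + tr$shift
    cx_t <- coords[atom_index(topo, acc, acc_res$acceptor_atom), ]
    ref_t <- coords[atom_index(topo, acc, acc_res$psi_ref_atom), ]

    don_res <- topo$residues[[don]]
    c1_t <- nerf_place(ref_t, cx_t, o1_t, BOND_ANOMERIC, ANGLE_GLYCOSIDIC,
                       par$psi[k])
    o5_t <- nerf_place(cx_t, o1_t, c1_t, don_res$d_c1_o5,
                       don_res$ang_o5_c1_o1, par$phi[k])

    dx <- local_xyz[[don]]
    from <- rbind(dx["C1", ], dx["O1", ], dx["O5", ])
    to <- rbind(c1_t, o1_t, o5_t)
    tf <- frame_transform(from, to)
    placed <- dx %*% t(tf$r)
    placed <- sweep(placed, 2, tf$shift, `+`)
    coords[(topo$offsets[don] + 1):topo$offsets[don + 1], ] <- placed
    transforms[[don]] <- tf
  }
  coords
}

apply_exo_torsion <- function(xyz, ex, target) {
  if (is.null(target) || is.na(target)) return(xyz)
  cur <- measure_torsion(xyz[ex$ref[1], ], xyz[ex$axis[1], ],
                         xyz[ex$axis[2], ], xyz[ex$ref[2], ])
  delta <- wrap_angle(target - cur)
  idx <- match(ex$group, rownames(xyz))
  rotate_about_axis(xyz, idx, xyz[ex$axis[1], ], xyz[ex$axis[2], ], delta)
}

default_par <- function(topo) {
  n_link <- topo$length - 1
  n_gal <- sum(vapply(topo$residues, function(r) r$kind == "GalNAc", logical(1)))
  # default glycosidic torsions: the canonical extended chondroitin geometry
  phi <- rep(-73, n_link)
  psi <- ifelse(seq_len(n_link) %% 2 == 1, 108, -117)
  list(phi = phi, psi = psi,
       omega = rep(180, n_gal), acetamido = rep(180, n_gal))
}

#' Assemble a chondroitin oligosaccharide chain
#'
#' Builds an alternating GalNAc/GlcA chain (reducing-end GalNAc first) with
#' the requested glycosidic torsions. Odd-numbered linkages are beta(1->3)
#' (GlcA C1 -> GalNAc O3), even-numbered are beta(1->4) (GalNAc C1 -> GlcA
#' O4), as in the chondroitin repeat. Residues are rigid 4C1 templates;
#' requested torsions are reproduced exactly by construction (set-then-measure
#' round-trips to well below 1e-6 degrees).
#'
#' @param length Number of residues; must be an even number >= 2 (the CN_n
#'   naming requires whole disaccharide repeats).
#' @param torsions A data frame (or tibble) with numeric columns `phi` and
#'   `psi`, one row per linkage (`length - 1` rows), in degrees. `NULL` uses
#'   the canonical extended chondroitin geometry.
#' @param anomer Reducing-end GalNAc configuration, `"beta"` or `"alpha"`.
#' @param omega,acetamido Optional numeric vectors (one value per GalNAc
#'   residue) of exocyclic hydroxymethyl and acetamido torsions in degrees;
#'   default 180 (trans).
#' @param check_clashes If `TRUE` (default), warn when two non-bonded heavy
#'   atoms end up closer than 1.5 angstroms.
#' @return A `glycan_model`: a tibble of atoms (columns `residue`, `kind`,
#'   `label`, `atom`, `element`, `x`, `y`, `z`) carrying the linkage table and
#'   torsion parameters as attributes.
#' @examples
#' cn2 <- assemble_chain(2, tibble::tibble(phi = -72, psi = 109))
#' measure_glycosidic_torsions(cn2)
#' @export
assemble_chain <- function(length, torsions = NULL,
                           anomer = c("beta", "alpha"),
                           omega = NULL, acetamido = NULL,
                           check_clashes = TRUE) {
  anomer <- match.arg(anomer)
  if (length < 2 || length %% 2 != 0) {
    stop("chain length must be an even number >= 2 (CN_n nomenclature)",
         call. = FALSE)
  }
  topo <- chain_topology(length, anomer)
  par <- default_par(topo)
  if (!is.null(torsions)) {
    torsions <- as.data.frame(torsions)
    if (nrow(torsions) != length - 1) {
      stop("need one (phi, psi) row per linkage: expected ", length - 1,
           ", got ", nrow(torsions), call. = FALSE)
    }
    stopifnot(all(c("phi", "psi") %in% names(torsions)))
    par$phi <- as.numeric(torsions$phi)
    par$psi <- as.numeric(torsions$psi)
  }
  if (!is.null(omega)) {
    stopifnot(length(omega) == length(par$omega))
    par$omega <- omega
  }
  if (!is.null(acetamido)) {
    stopifnot(length(acetamido) == length(par$acetamido))
    par$acetamido <- acetamido
  }
  new_glycan_model(topo, par, check_clashes = check_clashes)
}

new_glycan_model <- function(topo, par, coords = NULL, check_clashes = FALSE) {
  if (is.null(coords)) coords <- chain_coords(topo, par)
  atoms <- topo$atoms
  atoms$x <- coords[, 1]
  atoms$y <- coords[, 2]
  atoms$z <- coords[, 3]
  out <- tibble::new_tibble(
    atoms, nrow = nrow(atoms), class = "glycan_model",
    topology = topo, par = par, anomer = topo$anomer
  )
  if (check_clashes) {
    cl <- model_clashes(out)
    if (nrow(cl) > 0) {
      warning(nrow(cl), " non-bonded heavy-atom pair(s) closer than 1.5 A ",
              "(closest: ", cl$label_a[1], ":", cl$atom_a[1], " - ",
              cl$label_b[1], ":", cl$atom_b[1], " at ",
              round(cl$distance[1], 2), " A)", call. = FALSE)
    }
  }
  out
}

#' @export
print.glycan_model <- function(x, ...) {
  topo <- attr(x, "topology")
  cat("<glycan_model> CN_", topo$length, " (", nrow(x), " atoms, ",
      nrow(topo$linkages), " linkages, reducing-end ",
      attr(x, "anomer"), ")\n", sep = "")
  NextMethod()
}

model_topology <- function(model) attr(model, "topology")

model_xyz <- function(model) {
  as.matrix(tibble::as_tibble(model)[, c("x", "y", "z")])
}

# distances between non-bonded (graph separation > 3) heavy atoms below 1.5 A
model_clashes <- function(model) {
  topo <- model_topology(model)
  xyz <- model_xyz(model)
  pr <- topo$steric_pairs
  d <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                       xyz[pr[, 2], , drop = FALSE])^2))
  bad <- which(d < 1.5)
  tibble::tibble(
    label_a = topo$atoms$label[pr[bad, 1]], atom_a = topo$atoms$atom[pr[bad, 1]],
    label_b = topo$atoms$label[pr[bad, 2]], atom_b = topo$atoms$atom[pr[bad, 2]],
    distance = d[bad]
  ) |> dplyr::arrange(.data$distance)
}

# Resolve a (residue label, atom name) pair to a coordinate row.
model_atom <- function(model, label, atom) {
  hit <- which(model$label == label & model$atom == atom)
  if (length(hit) != 1) {
    stop("atom ", label, ":", atom, " not found in model", call. = FALSE)
  }
  c(model$x[hit], model$y[hit], model$z[hit])
}

model_distance <- function(model, label_a, atom_a, label_b, atom_b) {
  vnorm(model_atom(model, label_a, atom_a) - model_atom(model, label_b, atom_b))
}

glycosidic_quadruples <- function(topo, k) {
  lk <- topo$linkages[k, ]
  don <- lk$donor_label
  acc <- lk$acceptor_label
  if (lk$type == "b13") {
    list(phi = list(c(don, "O5"), c(don, "C1"), c(don, "O1"), c(acc, "C3")),
         psi = list(c(don, "C1"), c(don, "O1"), c(acc, "C3"), c(acc, "C4")))
  } else {
    list(phi = list(c(don, "O5"), c(don, "C1"), c(don, "O1"), c(acc, "C4")),
         psi = list(c(don, "C1"), c(don, "O1"), c(acc, "C4"), c(acc, "C5")))
  }
}

#' Measure glycosidic torsions of a model
#'
#' Returns the IUPAC glycosidic torsions of every linkage:
#' for beta(1->3) linkages phi = O5(U)-C1(U)-O1(U)-C3(N) and
#' psi = C1(U)-O1(U)-C3(N)-C4(N); for beta(1->4) linkages
#' phi = O5(N)-C1(N)-O1(N)-C4(U) and psi = C1(N)-O1(N)-C4(U)-C5(U).
#'
#' @param model A `glycan_model`.
#' @return A tibble with columns `linkage`, `type`, `donor_label`,
#'   `acceptor_label`, `phi`, `psi` (degrees in (-180, 180]).
#' @export
measure_glycosidic_torsions <- function(model) {
  topo <- model_topology(model)
  purrr::map_dfr(seq_len(nrow(topo$linkages)), function(k) {
    q <- glycosidic_quadruples(topo, k)
    pt <- function(spec) model_atom(model, spec[1], spec[2])
    tibble::tibble(
      linkage = k,
      type = topo$linkages$type[k],
      donor_label = topo$linkages$donor_label[k],
      acceptor_label = topo$linkages$acceptor_label[k],
      phi = measure_torsion(pt(q$phi[[1]]), pt(q$phi[[2]]),
                            pt(q$phi[[3]]), pt(q$phi[[4]])),
      psi = measure_torsion(pt(q$psi[[1]]), pt(q$psi[[2]]),
                            pt(q$psi[[3]]), pt(q$psi[[4]]))
    )
  })
}

#' Ring pucker torsions
#'
#' The six endocyclic torsions over consecutive ring-atom quadruples
#' (O5-C1-C2-C3, C1-C2-C3-C4, ..., C5-O5-C1-C2). In an ideal 4C1 chair they
#' alternate near +60 / -60 degrees; values outside the 60 +/- 20 degree
#' windows flag a non-chair ring.
#'
#' @param x A `glycan_residue` template or a `glycan_model`.
#' @return A tibble with columns `residue`, `label`, `index`, `atoms`,
#'   `expected_sign`, `angle` (degrees).
#' @export
ring_pucker_torsions <- function(x) {
  UseMethod("ring_pucker_torsions")
}

#' @export
ring_pucker_torsions.glycan_residue <- function(x) {
  xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
  rownames(xyz) <- x$atoms$atom
  ring_torsions_from_xyz(xyz, residue = 1L, label = x$kind)
}

#' @export
ring_pucker_torsions.glycan_model <- function(x) {
  xyz <- model_xyz(x)
  purrr::map_dfr(unique(x$residue), function(i) {
    idx <- which(x$residue == i)
    sub <- xyz[idx, , drop = FALSE]
    rownames(sub) <- x$atom[idx]
    ring_torsions_from_xyz(sub, residue = i, label = x$label[idx][1])
  })
}

ring_torsions_from_xyz <- function(xyz, residue, label) {
  quads <- ring_quadruples()
  missing <- setdiff(unique(unlist(quads)), rownames(xyz))
  if (length(missing) > 0) {
    stop("broken ring: missing atom(s) ", paste(missing, collapse = ", "),
         " in residue ", label, call. = FALSE)
  }
  p <- do.call(rbind, lapply(quads, function(q) {
    c(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
  }))
  tibble::tibble(
    residue = residue, label = label, index = seq_len(6),
    atoms = vapply(quads, paste, character(1), collapse = "-"),
    expected_sign = RING_SIGNS,
    angle = measure_torsion_many(p)
  )
}
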