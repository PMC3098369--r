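# File formats: multi-model PDB ensembles (the deposition format for NMR
# ensembles), TSV peak/restraint tables and CSV shift tables. All tables are
# UTF-8 with a single header row; units are embedded in the column names
# where ambiguous.

#' Default PDB residue-name mapping for glycosaminoglycan residues
#'
#' GAG residue naming in PDB files is inconsistent across depositions; this
#' table maps the common three-letter codes onto the two residue kinds used
#' here. Extend or override via the `residue_map` argument of
#' [read_multimodel_pdb()].
#'
#' @return A named character vector: PDB residue name -> `GalNAc` / `GlcA`.
#' @export
pdb_residue_map <- function() {
  c(NGA = "GalNAc", A2G = "GalNAc", NG6 = "GalNAc", GALNAC = "GalNAc",
    BDP = "GlcA", GCU = "GlcA", GCV = "GlcA", GLCA = "GlcA",
    UYB = "GlcA")
}

parse_pdb_atom_line <- function(line, lineno) {
  if (nchar(line) < 54) {
    stop("malformed ATOM record at line ", lineno, " (too short)",
         call. = FALSE)
  }
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (anyNA(xyz)) {
    stop("malformed coordinates at line ", lineno, call. = FALSE)
  }
  el <- trimws(substr(line, 77, 78))
  name <- trimws(substr(line, 13, 16))
  if (!nzchar(el)) el <- element_of(name)
  list(
    name = name,
    resname = trimws(substr(line, 18, 20)),
    resseq = suppressWarnings(as.integer(substr(line, 23, 26))),
    x = xyz[1], y = xyz[2], z = xyz[3],
    element = el
  )
}

#' Read a multi-model PDB file into a list of models
#'
#' Parses MODEL/ENDMDL-delimited coordinate blocks (or a single un-delimited
#' model) and maps PDB residue names to `GalNAc`/`GlcA` via the residue map.
#' Residues are renumbered sequentially from the first residue encountered
#' (the reducing end in the files written by this package) and labelled
#' N1/U2/... by kind.
#'
#' @param path Path to a PDB file.
#' @param residue_map Named character vector mapping PDB residue names to
#'   residue kinds; defaults to [pdb_residue_map()].
#' @return A list of `glycan_model`s (coordinates at PDB precision).
#' @export
read_multimodel_pdb <- function(path, residue_map = pdb_residue_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  model_ends <- which(trimws(rec) == "ENDMDL")

  blocks <- if (length(model_starts) == 0) {
    list(seq_along(lines))
  } else {
    if (length(model_ends) < length(model_starts)) {
      stop("truncated MODEL block: model ", length(model_starts),
           " has no ENDMDL", call. = FALSE)
    }
    purrr::map2(model_starts, model_ends, function(s, e) {
      if (e < s) stop("malformed MODEL/ENDMDL nesting near line ", s,
                      call. = FALSE)
      s:e
    })
  }

  purrr::map(seq_along(blocks), function(bi) {
    idx <- blocks[[bi]]
    atom_lines <- idx[trimws(rec[idx]) %in% c("ATOM", "HETATM")]
    if (length(atom_lines) == 0) {
      stop("model ", bi, " contains no coordinate records", call. = FALSE)
    }
    parsed <- purrr::map(atom_lines, function(ln) {
      parse_pdb_atom_line(lines[ln], ln)
    })
    tab <- tibble::tibble(
      atom = vapply(parsed, `[[`, character(1), "name"),
      resname = vapply(parsed, `[[`, character(1), "resname"),
      resseq = vapply(parsed, `[[`, integer(1), "resseq"),
      element = vapply(parsed, `[[`, character(1), "element"),
      x = vapply(parsed, `[[`, numeric(1), "x"),
      y = vapply(parsed, `[[`, numeric(1), "y"),
      z = vapply(parsed, `[[`, numeric(1), "z")
    )
    kinds <- unname(residue_map[toupper(tab$resname)])
    if (anyNA(kinds)) {
      bad <- unique(tab$resname[is.na(kinds)])
      stop("unmapped PDB residue name(s): ", paste(bad, collapse = ", "),
           " (extend residue_map)", call. = FALSE)
    }
    tab$kind <- kinds
    # sequential residue index in order of appearance
    tab$residue <- match(tab$resseq, unique(tab$resseq))
    tab$label <- paste0(ifelse(tab$kind == "GalNAc", "N", "U"), tab$residue)
    model_from_atoms(tab[, c("residue", "kind", "label", "atom", "element",
                             "x", "y", "z")])
  })
}

# Wrap an atom table into a glycan_model with a minimal topology (linkage
# table only) so the measurement and analysis functions work on models that
# were read from a file rather than assembled.
model_from_atoms <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  n_res <- length(unique(atoms$residue))
  kinds <- atoms$kind[!duplicated(atoms$residue)]
  linkages <- if (n_res >= 2) {
    tibble::tibble(
      linkage = seq_len(n_res - 1),
      donor = seq_len(n_res - 1) + 1L,
      acceptor = seq_len(n_res - 1),
      type = ifelse(kinds[seq_len(n_res - 1)] == "GalNAc", "b13", "b14")
    ) |>
      dplyr::mutate(
        donor_label = atoms$label[!duplicated(atoms$residue)][.data$donor],
        acceptor_label = atoms$label[!duplicated(atoms$residue)][.data$acceptor]
      )
  } else {
    tibble::tibble(linkage = integer(), donor = integer(),
                   acceptor = integer(), type = character(),
                   donor_label = character(), acceptor_label = character())
  }
  topo <- list(length = n_res, anomer = NA_character_, linkages = linkages,
               steric_pairs = NULL)
  tibble::new_tibble(atoms, nrow = nrow(atoms), class = "glycan_model",
                     topology = topo, par = NULL, anomer = NA_character_)
}

PDB_RESNAME <- c(GalNAc = "NGA", GlcA = "BDP")

format_pdb_atom <- function(serial, name, resname, resseq, x, y, z, element) {
  # left-justify 4-character names starting in column 14 (PDB convention for
  # names shorter than 4 characters)
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resname, resseq, x, y, z, 1, 0, element)
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' Models are written in energy-rank order inside MODEL/ENDMDL blocks;
#' REMARK 3 lines record the per-model energy, maximum restraint violation
#' and the ensemble seed.
#'
#' @param ensemble A `conformer_ensemble` (see [generate_ensemble()]) or any
#'   tibble with a `model` list-column (and optionally `energy`,
#'   `max_violation`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  models <- ensemble_models(ensemble)
  if (length(models) == 0) stop("empty ensemble", call. = FALSE)
  energy <- if ("energy" %in% names(ensemble)) ensemble$energy else
    rep(NA_real_, length(models))
  viol <- if ("max_violation" %in% names(ensemble)) ensemble$max_violation else
    rep(NA_real_, length(models))
  seed <- attr(ensemble, "ensemble_seed")

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "REMARK 3 RESTRAINED TORSION-SPACE SIMULATED ANNEALING ENSEMBLE",
    sprintf("REMARK 3 MODELS %d  SEED %s", length(models),
            if (is.null(seed)) "NA" else seed)
  ), con)
  for (i in seq_along(models)) {
    m <- models[[i]]
    writeLines(sprintf(
      "REMARK 3 MODEL %d ENERGY %s MAX_VIOLATION %s", i,
      formatC(energy[i], format = "f", digits = 4),
      formatC(viol[i], format = "f", digits = 4)
    ), con)
  }
  for (i in seq_along(models)) {
    m <- models[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    resname <- PDB_RESNAME[m$kind]
    lines <- vapply(seq_len(nrow(m)), function(a) {
      format_pdb_atom(a, m$atom[a], resname[a], m$residue[a],
                      m$x[a], m$y[a], m$z[a], m$element[a])
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read/write NOE peak and restraint tables
#'
#' Peak tables are TSV with columns `res_a`, `atom_a`, `res_b`, `atom_b`,
#' `intensity`, `multiplicity`, `role`; restraint tables are TSV with the
#' atom-pair columns plus `distance`, `bin`, `lower`, `upper`,
#' `force_constant` (all distances in angstroms).
#'
#' @param path File path.
#' @param peaks,restraints Tibbles to write.
#' @return A tibble (readers) or `path` invisibly (writers).
#' @name peak_io
NULL

#' @rdname peak_io
#' @export
read_noe_peaks <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname peak_io
#' @export
write_noe_peaks <- function(peaks, path) {
  readr::write_tsv(peaks, path)
  invisible(path)
}

#' @rdname peak_io
#' @export
read_restraints <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname peak_io
#' @export
write_restraints <- function(restraints, path) {
  readr::write_tsv(restraints, path)
  invisible(path)
}

#' Read a chemical-shift table
#'
#' CSV with identifying key columns (`ring`, `reporter`, `anomer`, ...) and
#' shift values in `delta_ppm` (or per-temperature columns for series data).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_shift_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
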