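#' Atom record table
#'
#' Atoms are represented throughout the package as plain data frames with
#' columns `atom_name`, `element`, `resno`, `resname`, `chain`, `x`, `y`, `z`
#' (coordinates in Angstrom). This constructor validates and normalizes such a
#' table.
#'
#' @param atom_name character vector of atom names (nonempty).
#' @param element character vector of element symbols; may be `NA`, in which
#'   case downstream heavy-atom logic falls back to the atom-name leading
#'   character.
#' @param resno integer residue numbers.
#' @param resname three-letter residue codes.
#' @param chain chain identifiers.
#' @param x,y,z finite coordinates in Angstrom.
#' @return a data.frame of atom records.
#' @export
atom_table <- function(atom_name, element = NA_character_, resno = 1L,
                       resname = "LIG", chain = "A", x, y, z) {
  df <- data.frame(
    atom_name = as.character(atom_name),
    element = as.character(element),
    resno = as.integer(resno),
    resname = as.character(resname),
    chain = as.character(chain),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(df$atom_name)) || anyNA(df$atom_name)) {
    stop("atom_name must be nonempty", call. = FALSE)
  }
  if (!all(is.finite(c(df$x, df$y, df$z)))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  df
}

#' Receptor structure with FAD cofactor
#'
#' Container holding the protein atoms and the FAD cofactor atoms of one
#' receptor model, partitioned by residue name.
#'
#' @param protein_atoms atom table of protein atoms (nonempty).
#' @param fad_atoms atom table of cofactor atoms; may be empty, in which case
#'   operations that need the FAD reference atom will error.
#' @param enzyme_id identifier of the enzyme.
#' @return an object of class `complex_structure`.
#' @export
complex_structure <- function(protein_atoms, fad_atoms, enzyme_id = "enzyme") {
  if (nrow(protein_atoms) == 0L) {
    stop("empty structure: no protein atoms", call. = FALSE)
  }
  structure(
    list(protein = protein_atoms, fad = fad_atoms, enzyme_id = enzyme_id),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf(
    "<complex_structure> %s: %d protein atoms (%d residues), %d FAD atoms\n",
    x$enzyme_id, nrow(x$protein),
    nrow(unique(x$protein[, c("chain", "resno")])), nrow(x$fad)
  ))
  invisible(x)
}

#' Single docked ligand pose
#'
#' @param pose_id integer pose identifier.
#' @param atoms atom table of ligand heavy atoms (at least 3).
#' @param energy docking energy in kcal/mol (finite).
#' @return an object of class `pose`.
#' @export
pose <- function(pose_id, atoms, energy) {
  if (nrow(atoms) < 3L) {
    stop("a pose needs at least 3 ligand atoms", call. = FALSE)
  }
  if (!is.finite(energy)) stop("pose energy must be finite", call. = FALSE)
  structure(list(pose_id = as.integer(pose_id), atoms = atoms,
                 energy = as.numeric(energy)),
            class = "pose")
}

#' Docked pose ensemble for one enzyme-ligand pair
#'
#' Poses are stored sorted by ascending energy. All poses must share an
#' identical atom-name vector in identical order; this is what makes the
#' fixed-frame RMSD used by [cluster_poses()] well defined.
#'
#' @param poses list of [pose()] objects (nonempty).
#' @param enzyme_id,ligand_id identifiers.
#' @return an object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(poses, enzyme_id = "enzyme", ligand_id = "ligand") {
  if (length(poses) == 0L) stop("empty pose ensemble", call. = FALSE)
  ref <- poses[[1L]]$atoms$atom_name
  ok <- vapply(poses, function(p) identical(p$atoms$atom_name, ref), logical(1))
  if (!all(ok)) {
    stop("inconsistent atom sets across poses", call. = FALSE)
  }
  energies <- vapply(poses, `[[`, numeric(1), "energy")
  poses <- unname(poses[order(energies)])
  structure(list(enzyme_id = enzyme_id, ligand_id = ligand_id, poses = poses),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  e <- pose_energies(x)
  cat(sprintf("<pose_ensemble> %s / %s: %d poses, %d atoms, E in [%.2f, %.2f] kcal/mol\n",
              x$enzyme_id, x$ligand_id, length(x$poses),
              nrow(x$poses[[1L]]$atoms), min(e), max(e)))
  invisible(x)
}

#' @rdname pose_ensemble
#' @param ensemble a `pose_ensemble`.
#' @export
pose_energies <- function(ensemble) {
  vapply(ensemble$poses, `[[`, numeric(1), "energy")
}

bio3d_to_atoms <- function(atom_df) {
  atom_table(
    atom_name = trimws(atom_df$elety),
    element = ifelse(is.na(atom_df$elesy), NA_character_, trimws(atom_df$elesy)),
    resno = atom_df$resno,
    resname = trimws(atom_df$resid),
    chain = ifelse(is.na(atom_df$chain), "A", atom_df$chain),
    x = atom_df$x, y = atom_df$y, z = atom_df$z
  )
}

#' Read a receptor PDB and partition protein vs FAD atoms
#'
#' @param path path to a PDB file.
#' @param fad_residue_names residue names treated as the FAD cofactor.
#' @param enzyme_id identifier recorded in the returned structure; defaults to
#'   the file base name.
#' @return a [complex_structure()].
#' @export
read_receptor_structure <- function(path, fad_residue_names = c("FAD", "FDA"),
                                    enzyme_id = NULL) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("unparseable PDB file: ", conditionMessage(e),
                             call. = FALSE)
  )
  atoms <- bio3d_to_atoms(pdb$atom)
  is_fad <- atoms$resname %in% fad_residue_names
  # water is neither protein nor cofactor
  is_water <- atoms$resname %in% c("HOH", "WAT", "TIP3")
  fad <- atoms[is_fad, , drop = FALSE]
  prot <- atoms[!is_fad & !is_water, , drop = FALSE]
  if (nrow(prot) == 0L) stop("empty structure: no protein atoms", call. = FALSE)
  if (nrow(fad) == 0L) {
    warning("no FAD residue (", paste(fad_residue_names, collapse = ", "),
            ") found in ", path, call. = FALSE)
  }
  complex_structure(prot, fad,
                    enzyme_id = enzyme_id %||%
                      sub("\\.[^.]*$", "", basename(path)))
}

#' Read a docked pose ensemble
#'
#' Two on-disk dialects are supported: a multi-model PDB (one `MODEL` per pose,
#' energy on a `REMARK ENERGY <kcal/mol>` line inside each model, or in the
#' B-factor column of the first atom), and a flat pose table (CSV with columns
#' `pose_id`, `atom_name`, `element`, `x`, `y`, `z`, `energy`). Only heavy
#' atoms are retained; poses are returned sorted by ascending energy.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"table"`.
#' @param energy_source for the PDB dialect, `"remark"` (default) or
#'   `"bfactor"`.
#' @param enzyme_id,ligand_id identifiers for the returned ensemble.
#' @return a [pose_ensemble()].
#' @export
read_pose_ensemble <- function(path, format = c("auto", "pdb", "table"),
                               energy_source = c("remark", "bfactor"),
                               enzyme_id = "enzyme", ligand_id = "ligand") {
  format <- match.arg(format)
  energy_source <- match.arg(energy_source)
  if (format == "auto") {
    format <- if (grepl("\\.(csv|tsv|txt)$", path, ignore.case = TRUE))
      "table" else "pdb"
  }
  if (format == "table") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("pose_id", "atom_name", "x", "y", "z", "energy")
    if (!all(need %in% names(tab))) {
      stop("pose table missing columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
    }
    if (anyNA(tab$energy)) stop("missing energies in pose table", call. = FALSE)
    if (is.null(tab$element)) tab$element <- NA_character_
    poses <- lapply(split(tab, tab$pose_id), function(d) {
      d <- d[is_heavy_atom(d$element, d$atom_name), , drop = FALSE]
      pose(d$pose_id[1L],
           atom_table(d$atom_name, d$element, x = d$x, y = d$y, z = d$z),
           energy = d$energy[1L])
    })
    return(pose_ensemble(poses, enzyme_id = enzyme_id, ligand_id = ligand_id))
  }
  # multi-model PDB
  lines <- readLines(path, warn = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("unparseable PDB file: ", conditionMessage(e),
                             call. = FALSE)
  )
  n_models <- max(1L, nrow(pdb$xyz))
  atoms <- bio3d_to_atoms(pdb$atom)
  heavy <- is_heavy_atom(atoms$element, atoms$atom_name)
  if (energy_source == "remark") {
    en_lines <- grep("^REMARK\\s+ENERGY\\s+", lines, value = TRUE)
    energies <- suppressWarnings(
      as.numeric(sub("^REMARK\\s+ENERGY\\s+(\\S+).*$", "\\1", en_lines)))
    if (length(energies) != n_models || anyNA(energies)) {
      stop("missing or malformed REMARK ENERGY records (", length(energies),
           " for ", n_models, " models)", call. = FALSE)
    }
  } else {
    b <- pdb$atom$b
    if (is.null(b) || anyNA(b[1L])) {
      stop("missing B-factor energy channel", call. = FALSE)
    }
    # first atom's B-factor per model; bio3d keeps one atom table, so the
    # B-factor channel is only usable when energies repeat across models
    energies <- rep(b[1L], n_models)
    # per-model B-factors are available from raw lines when models differ
    bf <- bfactor_energies(lines)
    if (length(bf) == n_models) energies <- bf
  }
  poses <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    a <- atoms
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
    a <- a[heavy, , drop = FALSE]
    pose(m, a, energy = energies[m])
  })
  pose_ensemble(poses, enzyme_id = enzyme_id, ligand_id = ligand_id)
}

# First-atom B-factor of every MODEL, read from raw PDB lines.
bfactor_energies <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) model_starts <- 1L
  vapply(model_starts, function(i) {
    j <- i
    repeat {
      j <- j + 1L
      if (j > length(lines)) return(NA_real_)
      if (grepl("^(ATOM|HETATM)", lines[j])) {
        return(suppressWarnings(as.numeric(substr(lines[j], 61, 66))))
      }
    }
  }, numeric(1))
}

#' Write a pose ensemble
#'
#' Inverse of [read_pose_ensemble()]. The PDB dialect stores coordinates at
#' the standard 3-decimal PDB precision with one `REMARK ENERGY` line per
#' model; the table dialect round-trips energies exactly.
#'
#' @param ensemble a [pose_ensemble()].
#' @param path output file.
#' @param format `"pdb"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_pose_ensemble <- function(ensemble, path, format = c("pdb", "table")) {
  format <- match.arg(format)
  if (format == "table") {
    # %.17g keeps doubles exact through the text round trip
    rows <- do.call(rbind, lapply(ensemble$poses, function(p) {
      data.frame(pose_id = p$pose_id, atom_name = p$atoms$atom_name,
                 element = p$atoms$element,
                 x = sprintf("%.17g", p$atoms$x),
                 y = sprintf("%.17g", p$atoms$y),
                 z = sprintf("%.17g", p$atoms$z),
                 energy = sprintf("%.17g", p$energy),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, path, row.names = FALSE, quote = FALSE,
                       sep = ",")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (p in ensemble$poses) {
    writeLines(sprintf("MODEL     %4d", p$pose_id), con)
    writeLines(sprintf("REMARK ENERGY %.6f", p$energy), con)
    a <- p$atoms
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)), substr(a$atom_name, 1, 4), substr(a$resname, 1, 3),
      substr(a$chain, 1, 1), a$resno, a$x, a$y, a$z,
      ifelse(is.na(a$element), "", a$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read and validate a screen annotation table
#'
#' Expects a CSV with columns `enzyme_id`, `ligand_id`, `stereochemistry`
#' (one of `R`, `S`, `R/S`, or `NA`/empty for not assayed / no conversion) and
#' `conversion` (fraction or 0/1 flag).
#'
#' @param path CSV file.
#' @return a validated data.frame.
#' @export
read_screen_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(stereochemistry = "character"))
  need <- c("enzyme_id", "ligand_id", "stereochemistry", "conversion")
  if (nrow(tab) == 0L) {
    warning("empty screen table: ", path, call. = FALSE)
    for (n in setdiff(need, names(tab))) tab[[n]] <- character(0)
    return(tab[, need, drop = FALSE])
  }
  if (!all(need %in% names(tab))) {
    stop("screen table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  st <- toupper(trimws(tab$stereochemistry))
  st[st == "" | st == "NA"] <- NA_character_
  bad <- !is.na(st) & !(st %in% c("R", "S", "R/S"))
  if (any(bad)) {
    stop("unknown stereochemistry token(s): ",
         paste(unique(st[bad]), collapse = ", "), call. = FALSE)
  }
  tab$stereochemistry <- st
  tab$conversion <- as.numeric(tab$conversion)
  tab
}
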