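# Van der Waals radii (Angstrom) by element, Bondi-style values.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90)
VDW_DEFAULT <- 1.70

# Theoretical maximum accessible surface areas (Angstrom^2) per residue,
# Tien et al. (2013) Gly-X-Gly values, used to normalize absolute SASA.
MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
             GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
             LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
             SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral), the quadrature grid of the Shrake-Rupley method.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric SASA by the Shrake-Rupley rolling-probe method: each atom is
#' expanded by the probe radius, a deterministic quasi-uniform point grid is
#' placed on the expanded sphere, points falling inside any neighboring
#' expanded sphere are occluded, and the accessible fraction times the
#' sphere area is summed per residue. Relative SASA divides the residue
#' total by the Tien et al. theoretical Gly-X-Gly maximum for that residue
#' type (values may slightly exceed 1 for exposed termini; they are reported
#' uncapped with a `rel_sasa_capped` column available via `pmin`).
#'
#' @param structure a `bio3d` `pdb` object, a path to a PDB file, or a data
#'   frame of atoms with columns `chain`, `resno`, `resid`, `elety`, `x`,
#'   `y`, `z` and optionally `elesy` (element symbol) and `insert`.
#' @param probe_radius probe radius in Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (default 242).
#' @param chain optional chain id(s) to restrict the computation to; other
#'   chains are removed entirely (they then do not occlude).
#' @param keep_hydrogens include hydrogens if present (default FALSE).
#' @return data frame of class `residue_accessibility`: `chain`, `resno`,
#'   `insert`, `resid`, `n_atoms`, `sasa` (absolute, A^2), `rel_sasa`.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 242,
                         chain = NULL, keep_hydrogens = FALSE) {
  atoms <- as_atom_table(structure)
  if (!is.null(chain)) {
    if (!any(atoms$chain %in% chain)) {
      stop("chain(s) not found in structure: ",
           paste(setdiff(chain, unique(atoms$chain)), collapse = ", "),
           call. = FALSE)
    }
    atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  }
  if (!keep_hydrogens) {
    atoms <- atoms[atoms$element != "H", , drop = FALSE]
  }
  n <- nrow(atoms)
  if (n == 0L) stop("no atoms to compute SASA on", call. = FALSE)
  radii <- VDW_RADII[atoms$element]
  radii[is.na(radii)] <- VDW_DEFAULT
  radii <- unname(radii) + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  max_r <- max(radii)
  # neighbor search on a coarse grid to avoid the O(n^2) distance matrix
  cell <- 2 * max_r
  key <- paste(floor(xyz[, 1] / cell), floor(xyz[, 2] / cell),
               floor(xyz[, 3] / cell))
  cells <- split(seq_len(n), key)
  cell_index <- do.call(rbind, strsplit(names(cells), " "))
  storage.mode(cell_index) <- "integer"
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(cells)) assign(names(cells)[k], cells[[k]], envir = lookup)
  area <- numeric(n)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(n)) {
    ci <- floor(xyz[i, ] / cell)
    nb <- integer(0)
    for (o in seq_len(nrow(offsets))) {
      kk <- paste(ci[1] + offsets[o, 1], ci[2] + offsets[o, 2],
                  ci[3] + offsets[o, 3])
      if (!is.null(v <- lookup[[kk]])) nb <- c(nb, v)
    }
    nb <- nb[nb != i]
    if (length(nb)) {
      d2 <- rowSums((xyz[nb, , drop = FALSE] -
                       matrix(xyz[i, ], length(nb), 3, byrow = TRUE))^2)
      nb <- nb[d2 < (radii[i] + radii[nb])^2]
    }
    sp <- pts * radii[i]
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj <- sweep(sp[accessible, , drop = FALSE], 2, xyz[j, ], `-`)
      inside <- rowSums(dj^2) < radii[j]^2
      accessible[accessible] <- !inside
    }
    area[i] <- mean(accessible) * 4 * pi * radii[i]^2
  }
  atoms$atom_sasa <- area
  res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  agg <- stats::aggregate(atom_sasa ~ res_key, data = atoms, FUN = sum)
  first <- atoms[!duplicated(res_key), c("chain", "resno", "insert", "resid")]
  first$res_key <- res_key[!duplicated(res_key)]
  out <- merge(first, agg, by = "res_key")
  out$n_atoms <- as.integer(table(res_key)[out$res_key])
  out$sasa <- out$atom_sasa
  out$rel_sasa <- out$sasa / MAX_ASA[out$resid]
  out <- out[order(out$chain, out$resno, out$insert),
             c("chain", "resno", "insert", "resid", "n_atoms", "sasa",
               "rel_sasa")]
  rownames(out) <- NULL
  class(out) <- c("residue_accessibility", class(out))
  out
}

as_atom_table <- function(structure) {
  if (is.character(structure) && length(structure) == 1L) {
    if (!file.exists(structure)) {
      stop("PDB file not found: ", structure, call. = FALSE)
    }
    structure <- bio3d::read.pdb(structure)
  }
  if (inherits(structure, "pdb")) {
    a <- structure$atom
    a <- a[a$type == "ATOM", , drop = FALSE]
    df <- data.frame(chain = a$chain, resno = a$resno,
                     insert = ifelse(is.na(a$insert), "", a$insert),
                     resid = a$resid, elety = a$elety,
                     element = guess_element(a),
                     x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
    return(df)
  }
  if (is.data.frame(structure)) {
    need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
    miss <- setdiff(need, names(structure))
    if (length(miss)) {
      stop("atom table missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    df <- structure
    if (!"insert" %in% names(df)) df$insert <- ""
    if (!"element" %in% names(df)) {
      df$element <- substr(gsub("[0-9]", "", df$elety), 1, 1)
    }
    return(df)
  }
  stop("unsupported structure input", call. = FALSE)
}

guess_element <- function(atom) {
  if (!is.null(atom$elesy) && !all(is.na(atom$elesy)) &&
      !all(atom$elesy == "")) {
    el <- toupper(atom$elesy)
    el[is.na(el) | el == ""] <- substr(gsub("[0-9]", "",
                                            atom$elety[is.na(el) | el == ""]),
                                       1, 1)
    return(el)
  }
  substr(gsub("[0-9]", "", atom$elety), 1, 1)
}

#' Relative SASA at selected numbering labels
#'
#' Resolves Chothia-style numbering labels to residues of a chain through an
#' explicit label -> residue-number map and returns their relative SASA.
#'
#' @param accessibility a [compute_sasa()] result.
#' @param chain chain id to look in.
#' @param numbering_map named vector mapping numbering label -> PDB residue
#'   number (names are labels). For structures numbered directly in Chothia
#'   positions this is simply `setNames(labels, labels)`.
#' @param labels character vector of labels to report.
#' @return data frame `label`, `resno`, `resid`, `rel_sasa`.
#' @export
rsasa_at_positions <- function(accessibility, chain, numbering_map, labels) {
  resno <- numbering_map[labels]
  if (anyNA(resno)) {
    stop("label(s) not in numbering map: ",
         paste(labels[is.na(resno)], collapse = ", "), call. = FALSE)
  }
  sub <- accessibility[accessibility$chain == chain, , drop = FALSE]
  idx <- match(as.integer(resno), sub$resno)
  if (anyNA(idx)) {
    stop("label(s) unresolvable on chain ", chain, ": ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  data.frame(label = labels, resno = as.integer(resno),
             resid = sub$resid[idx], rel_sasa = sub$rel_sasa[idx],
             stringsAsFactors = FALSE)
}

#' Map a mutation profile onto structure residues
#'
#' Writes each numbering label's mutation frequency onto the corresponding
#' residue of a chain, producing a per-residue annotation table suitable for
#' the temperature-factor channel of a PDB file. Labels that do not resolve
#' to a residue are reported in the `unresolved` attribute; residues outside
#' the profile get frequency 0.
#'
#' @param profile a [shm_profile()] result.
#' @param accessibility a [compute_sasa()] result (supplies the residue
#'   list).
#' @param chain chain id to annotate.
#' @param numbering_map named vector label -> residue number (as in
#'   [rsasa_at_positions()]).
#' @return data frame `chain`, `resno`, `resid`, `rel_sasa`, `label`,
#'   `mutation_freq`; attribute `unresolved` lists labels with no residue.
#' @export
map_profile_to_structure <- function(profile, accessibility, chain,
                                     numbering_map) {
  stopifnot(inherits(profile, "mutation_profile"))
  sub <- accessibility[accessibility$chain == chain, , drop = FALSE]
  if (nrow(sub) == 0L) stop("chain not found: ", chain, call. = FALSE)
  resno_of_label <- numbering_map[profile$labels]
  resolvable <- !is.na(resno_of_label) &
    as.integer(resno_of_label) %in% sub$resno
  if (!any(resolvable)) {
    stop("no profile label resolves onto chain ", chain, call. = FALSE)
  }
  out <- sub[, c("chain", "resno", "resid", "rel_sasa")]
  out$label <- NA_character_
  out$mutation_freq <- 0
  lab <- profile$labels[resolvable]
  rn <- as.integer(resno_of_label[resolvable])
  idx <- match(rn, out$resno)
  out$label[idx] <- lab
  out$mutation_freq[idx] <- profile$per_position_freq[lab]
  attr(out, "unresolved") <- profile$labels[!resolvable]
  rownames(out) <- NULL
  out
}

#' Write a structure annotation table as TSV
#'
#' @param annotation result of [map_profile_to_structure()] or
#'   [compute_sasa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
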