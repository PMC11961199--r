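#' Construct an enzyme record
#'
#' An `enzyme_record` holds one chain of an enzyme structure at residue
#' resolution: the amino-acid sequence, author residue identifiers
#' (number plus insertion code), Calpha coordinates, the per-atom table of
#' heavy atoms, catalytic labels and (optionally) the first-level EC class.
#'
#' @param id Structure identifier, conventionally `"<pdbid>_<chain>"`.
#' @param sequence One-letter amino-acid string of length `n`.
#' @param residue_numbers Character vector of author residue identifiers
#'   (e.g. `"100"`, `"100A"`), length `n`.
#' @param ca_coords Numeric `n x 3` matrix of Calpha coordinates in Angstrom.
#' @param atoms Tibble of heavy atoms with columns `res_index` (1-based
#'   residue index), `name`, `element`, `x`, `y`, `z`, `b` (B-factor) and
#'   `is_sidechain`.
#' @param catalytic_mask Integer/logical vector of length `n`; defaults to
#'   all zero.
#' @param ec_class First-level EC class in 1..7, or `NA`.
#'
#' @return An object of class `enzyme_record`.
#' @export
enzyme_record <- function(id, sequence, residue_numbers, ca_coords, atoms,
                          catalytic_mask = NULL, ec_class = NA_integer_) {
  n <- nchar(sequence)
  ca_coords <- as.matrix(ca_coords)
  if (is.null(catalytic_mask)) catalytic_mask <- integer(n)
  catalytic_mask <- as.integer(catalytic_mask)
  rec <- structure(
    list(id = id, sequence = sequence,
         residue_numbers = as.character(residue_numbers),
         ca_coords = ca_coords, atoms = tibble::as_tibble(atoms),
         catalytic_mask = catalytic_mask,
         ec_class = as.integer(ec_class)),
    class = "enzyme_record")
  validate_enzyme_record(rec)
  rec
}

validate_enzyme_record <- function(rec) {
  n <- nchar(rec$sequence)
  if (length(rec$residue_numbers) != n)
    abort("residue_numbers length does not match sequence length")
  if (nrow(rec$ca_coords) != n || ncol(rec$ca_coords) != 3)
    abort("ca_coords must be an n x 3 matrix matching the sequence length")
  if (length(rec$catalytic_mask) != n)
    abort("catalytic_mask length does not match sequence length")
  if (!all(rec$catalytic_mask %in% c(0L, 1L)))
    abort("catalytic_mask must be binary")
  if (n > 0) {
    counts <- tabulate(rec$atoms$res_index, nbins = n)
    if (any(counts == 0))
      abort(paste0("residues without any atom: ",
                   paste(which(counts == 0), collapse = ", ")))
  }
  invisible(rec)
}

#' @export
print.enzyme_record <- function(x, ...) {
  cat("<enzyme_record> ", x$id, ": ", nchar(x$sequence), " residues, ",
      nrow(x$atoms), " heavy atoms, ", sum(x$catalytic_mask),
      " catalytic", if (!is.na(x$ec_class))
        paste0(", EC class ", x$ec_class), "\n", sep = "")
  invisible(x)
}

#' Number of residues in a record or graph
#' @param x An `enzyme_record` or `residue_graph`.
#' @return Integer residue count.
#' @export
n_residues <- function(x) {
  if (inherits(x, "enzyme_record")) return(nchar(x$sequence))
  if (inherits(x, "residue_graph")) return(nrow(x$adjacency))
  abort("n_residues() expects an enzyme_record or residue_graph")
}

#' Read one chain of a PDB/mmCIF structure into an enzyme record
#'
#' Parses an atomic structure file, keeps the requested chain, and reduces
#' it to heavy-atom residue records: hydrogens, waters and hetero-compounds
#' are excluded, residues are ordered by author numbering, and residues
#' lacking a Calpha atom are dropped with a warning.
#'
#' @param path Path to a PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param chain Chain identifier; must exist in the file.
#'
#' @return An [enzyme_record()].
#' @export
read_structure <- function(path, chain) {
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  at <- pdb$atom
  chains <- sort(unique(at$chain))
  if (!(chain %in% chains))
    abort(paste0("chain '", chain, "' not found; available chains: ",
                 paste(chains, collapse = ", ")))
  at <- at[at$chain == chain & at$type == "ATOM", , drop = FALSE]
  # exclude hydrogens (element symbol H or D) and waters
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  keep <- !(elem %in% c("H", "D")) & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0) abort("no standard residues found in chain")

  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  res_key <- paste0(at$resno, ins)
  # author ordering: by residue number then insertion code
  ord_keys <- unique(data.frame(key = res_key, resno = at$resno, ins = ins,
                                stringsAsFactors = FALSE))
  ord_keys <- ord_keys[order(ord_keys$resno, ord_keys$ins), , drop = FALSE]

  recs <- lapply(seq_len(nrow(ord_keys)), function(i) {
    sel <- res_key == ord_keys$key[i]
    sub <- at[sel, , drop = FALSE]
    ca <- which(trimws(sub$elety) == "CA")
    list(key = ord_keys$key[i], sub = sub, elem = elem[sel], ca = ca)
  })
  has_ca <- vapply(recs, function(r) length(r$ca) >= 1, logical(1))
  if (any(!has_ca)) {
    warn(paste0("dropping ", sum(!has_ca),
                " residue(s) without a Calpha atom: ",
                paste(vapply(recs[!has_ca], `[[`, "", "key"),
                      collapse = ", ")))
    recs <- recs[has_ca]
  }
  if (length(recs) == 0) abort("no residues with Calpha atoms in chain")

  n <- length(recs)
  ca_coords <- t(vapply(recs, function(r) {
    i <- r$ca[1]
    c(r$sub$x[i], r$sub$y[i], r$sub$z[i])
  }, numeric(3)))
  seq1 <- vapply(recs, function(r) aa_three_to_one(r$sub$resid[1]), "")
  atoms <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    r <- recs[[i]]
    nm <- trimws(r$sub$elety)
    tibble::tibble(
      res_index = i, name = nm, element = r$elem,
      x = r$sub$x, y = r$sub$y, z = r$sub$z,
      b = ifelse(is.na(r$sub$b), 0, r$sub$b),
      is_sidechain = !(nm %in% c("N", "CA", "C", "O", "OXT")))
  }))
  id <- paste0(tools::file_path_sans_ext(basename(path)), "_", chain)
  enzyme_record(id = id, sequence = paste(seq1, collapse = ""),
                residue_numbers = vapply(recs, `[[`, "", "key"),
                ca_coords = ca_coords, atoms = atoms)
}

#' Calpha-Calpha contact map
#'
#' Binary residue adjacency: residues `i != j` are in contact when their
#' Calpha atoms lie within `cutoff` Angstrom. The result is symmetric with
#' a zero diagonal.
#'
#' @param record An [enzyme_record()], or an `n x 3` coordinate matrix.
#' @param cutoff Distance cutoff in Angstrom (default 10).
#'
#' @return `n x n` binary matrix.
#' @export
contact_map <- function(record, cutoff = 10) {
  xyz <- if (inherits(record, "enzyme_record")) record$ca_coords
         else as.matrix(record)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    abort("cutoff must be a single positive number")
  if (!all(is.finite(xyz))) abort("non-finite Calpha coordinates")
  d <- as.matrix(stats::dist(xyz))
  a <- (d <= cutoff) * 1
  diag(a) <- 0
  a
}

# Deterministic near-uniform unit sphere points (Fibonacci lattice).
fibonacci_sphere <- function(k) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessibility by the rolling-probe (Shrake-Rupley) method
#'
#' Approximates per-residue solvent-accessible surface area over heavy
#' atoms with a 1.4-Angstrom probe and a deterministic Fibonacci sphere
#' lattice per atom.
#'
#' @param record An [enzyme_record()].
#' @param probe Probe radius in Angstrom.
#' @param n_points Surface points per atom (accuracy/cost trade-off).
#'
#' @return Tibble with columns `abs_sasa` (Angstrom^2) and `rel_sasa`
#'   (absolute value over the residue-type theoretical maximum, clipped to
#'   `[0, 1]`), one row per residue.
#' @export
compute_sasa <- function(record, probe = 1.4, n_points = 92) {
  at <- record$atoms
  xyz <- cbind(at$x, at$y, at$z)
  radii <- element_vdw(at$element) + probe
  sphere <- fibonacci_sphere(n_points)
  m <- nrow(xyz)
  area <- numeric(m)
  # pairwise neighbor lists; m is small for single chains
  d2 <- as.matrix(stats::dist(xyz))^2
  rmax <- max(radii)
  for (i in seq_len(m)) {
    nb <- which(d2[i, ] < (radii[i] + rmax)^2)
    nb <- nb[nb != i]
    pts <- sweep(sphere * radii[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        acc <- acc & (dj >= radii[j]^2)
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    area[i] <- 4 * pi * radii[i]^2 * frac
  }
  n <- n_residues(record)
  abs_sasa <- vapply(seq_len(n), function(i) sum(area[at$res_index == i]),
                     numeric(1))
  aa <- strsplit(record$sequence, "")[[1]]
  rel <- pmin(abs_sasa / max_asa_for(aa), 1)
  tibble::tibble(abs_sasa = abs_sasa, rel_sasa = rel)
}

# Per-atom values of the first 11 atomic channels (averaged by
# atomic_descriptor); exposed internally so tests can re-average.
atom_channel_values <- function(atoms, sequence) {
  el <- atoms$element
  aa <- strsplit(sequence, "")[[1]]
  onehot <- cbind(C = as.numeric(el == "C"), N = as.numeric(el == "N"),
                  O = as.numeric(el == "O"), S = as.numeric(el == "S"))
  other <- as.numeric(!(el %in% c("C", "N", "O", "S")))
  ring <- logical(nrow(atoms))
  for (i in unique(atoms$res_index)) {
    sel <- atoms$res_index == i
    ring[sel] <- ring_membership(aa[i], atoms$is_sidechain[sel])
  }
  cbind(onehot, other = other,
        mass = element_mass(el), b = atoms$b,
        sidechain = as.numeric(atoms$is_sidechain),
        h_count = bonded_hydrogens(el, atoms$is_sidechain),
        ring = as.numeric(ring), vdw = element_vdw(el))
}

#' Per-residue atomic descriptor (14 channels)
#'
#' Averages atomic properties over each residue's heavy atoms and appends
#' residue-level solvent accessibility. Channel order is fixed:
#' 1-5 atom-type one-hot means (C, N, O, S, other); 6 atomic mass;
#' 7 B-factor; 8 side-chain fraction; 9 bonded-hydrogen count;
#' 10 ring-membership fraction; 11 van der Waals radius;
#' 12 relative SASA; 13 absolute SASA; 14 reserved (zero).
#'
#' @param record An [enzyme_record()].
#' @param sasa Optional per-residue accessibility: either a numeric vector
#'   of absolute SASA values (relative values derived from residue-type
#'   maxima) or a data frame with columns `abs_sasa` and `rel_sasa`. When
#'   omitted it is computed with [compute_sasa()].
#'
#' @return Numeric `n x 14` matrix.
#' @export
atomic_descriptor <- function(record, sasa = NULL) {
  n <- n_residues(record)
  if (is.null(sasa)) {
    sasa <- compute_sasa(record)
  } else if (is.numeric(sasa)) {
    if (length(sasa) != n)
      abort(paste0("sasa length ", length(sasa),
                   " does not match residue count ", n))
    aa <- strsplit(record$sequence, "")[[1]]
    sasa <- tibble::tibble(abs_sasa = sasa,
                           rel_sasa = pmin(sasa / max_asa_for(aa), 1))
  } else {
    sasa <- tibble::as_tibble(sasa)
    if (nrow(sasa) != n)
      abort(paste0("sasa has ", nrow(sasa), " rows but record has ", n,
                   " residues"))
  }
  vals <- atom_channel_values(record$atoms, record$sequence)
  xa <- matrix(0, n, 14)
  for (i in seq_len(n)) {
    sel <- record$atoms$res_index == i
    xa[i, 1:11] <- colMeans(vals[sel, , drop = FALSE])
  }
  xa[, 12] <- sasa$rel_sasa
  xa[, 13] <- sasa$abs_sasa
  colnames(xa) <- c("type_C", "type_N", "type_O", "type_S", "type_other",
                    "mass", "b_factor", "sidechain", "h_count", "ring",
                    "vdw", "rel_sasa", "abs_sasa", "reserved")
  xa
}

#' Assemble the attributed residue graph
#'
#' Combines the contact-map adjacency with the three feature blocks: the
#' evolutionary block `x_l` (sigmoid-normalized PSSM, 20 columns, followed
#' by the profile-HMM block, 30 columns), the language-model embedding
#' block `x_g` (`n x 1024`), and the atomic block `x_a` (`n x 14`). The
#' graph-convolution input `[x_l, x_a]` therefore always has width 64.
#'
#' @param record An [enzyme_record()].
#' @param profiles A [profile_set()] whose matrices have `n` rows.
#' @param embedding Optional `n x 1024` matrix; when `NULL` the block is
#'   zero-filled and the graph is flagged as having no embedding.
#' @param cutoff Contact-map cutoff in Angstrom.
#' @param sasa Optional accessibility passed to [atomic_descriptor()].
#'
#' @return An object of class `residue_graph`.
#' @export
build_graph <- function(record, profiles, embedding = NULL, cutoff = 10,
                        sasa = NULL) {
  n <- n_residues(record)
  stopifnot(inherits(profiles, "profile_set"))
  if (nrow(profiles$pssm) != n)
    abort(paste0("PSSM has ", nrow(profiles$pssm),
                 " rows but structure has ", n, " residues"))
  if (nrow(profiles$hmm) != n)
    abort(paste0("HMM profile has ", nrow(profiles$hmm),
                 " rows but structure has ", n, " residues"))
  embedded <- !is.null(embedding)
  if (embedded) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != n || ncol(embedding) != 1024)
      abort(paste0("embedding must be ", n, " x 1024; found ",
                   nrow(embedding), " x ", ncol(embedding)))
  } else {
    embedding <- matrix(0, n, 1024)
  }
  g <- structure(
    list(id = record$id,
         adjacency = contact_map(record, cutoff),
         x_l = cbind(profiles$pssm, profiles$hmm),
         x_g = embedding,
         x_a = atomic_descriptor(record, sasa),
         labels = record$catalytic_mask,
         ec_class = record$ec_class,
         ca_coords = record$ca_coords,
         residue_numbers = record$residue_numbers,
         embedded = embedded),
    class = "residue_graph")
  validate_residue_graph(g)
  g
}

validate_residue_graph <- function(g) {
  a <- g$adjacency
  n <- nrow(a)
  if (!isTRUE(all.equal(a, t(a)))) abort("adjacency must be symmetric")
  if (any(diag(a) != 0)) abort("adjacency diagonal must be zero")
  if (!all(a %in% c(0, 1))) abort("adjacency entries must be binary")
  if (nrow(g$x_l) != n || ncol(g$x_l) != 50)
    abort("x_l must be n x 50 (PSSM 20 + HMM 30)")
  if (any(g$x_l < 0 | g$x_l > 1)) abort("x_l entries must lie in [0, 1]")
  if (nrow(g$x_g) != n || ncol(g$x_g) != 1024)
    abort("x_g must be n x 1024")
  if (nrow(g$x_a) != n || ncol(g$x_a) != 14) abort("x_a must be n x 14")
  if (length(g$labels) != n) abort("labels length must equal n")
  invisible(g)
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("<residue_graph> ", x$id, ": n=", nrow(x$adjacency), ", ",
      sum(x$adjacency) / 2, " contacts, ", sum(x$labels), " catalytic, ",
      if (x$embedded) "with" else "without", " embedding\n", sep = "")
  invisible(x)
}

#' Write a contact map to disk
#'
#' @param a Binary adjacency matrix.
#' @param path Output file.
#' @param format `"dense"` (whitespace-separated 0/1 matrix) or
#'   `"edges"` (TSV of 1-based `i`, `j` pairs with `i < j`).
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(a, path, format = c("dense", "edges")) {
  format <- match.arg(format)
  if (format == "dense") {
    write.table(a, path, row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
    write.table(data.frame(i = idx[, 1], j = idx[, 2]), path, sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read catalytic labels and apply them to a record
#'
#' The label file is a TSV with columns `structure_id`, `chain`,
#' `residue_number`. Rows are matched to the record by chain-qualified id
#' and author residue number.
#'
#' @param record An [enzyme_record()].
#' @param path Label TSV.
#' @return The record with `catalytic_mask` set.
#' @export
apply_labels <- function(record, path) {
  lab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("structure_id", "chain", "residue_number")
  if (!all(need %in% names(lab)))
    abort("label file must have columns structure_id, chain, residue_number")
  key <- paste0(lab$structure_id, "_", lab$chain)
  lab <- lab[key == record$id, , drop = FALSE]
  mask <- as.integer(record$residue_numbers %in% lab$residue_number)
  record$catalytic_mask <- mask
  record
}
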