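# Canonical PSI-BLAST amino-acid column order for the 20 log-odds columns.
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Elementwise logistic (sigmoid) normalization
#'
#' Maps every entry `x` to `1 / (1 + exp(-x))`, the normalization applied
#' to raw PSSM log-odds before they enter the feature matrix. Shape is
#' preserved; finite input gives output strictly inside `(0, 1)`.
#'
#' @param m Numeric vector or matrix with finite entries.
#' @return Object of the same shape.
#' @export
sigmoid_normalize <- function(m) {
  if (!all(is.finite(m))) abort("sigmoid_normalize: entries must be finite")
  1 / (1 + exp(-m))
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the matrix written by `psiblast -out_ascii_pssm`: the 20 log-odds
#' columns in the canonical PSI-BLAST amino-acid order
#' (ARNDCQEGHILKMFPSTWYV). Trailing weighted-percentage and information
#' columns are ignored.
#'
#' @param path PSSM text file.
#' @return Integer `n x 20` matrix of raw log-odds, with the residue
#'   letters as an attribute `"residues"`.
#' @export
parse_pssm <- function(path) {
  if (!file.exists(path)) abort(paste0("PSSM file not found: ", path))
  lines <- readLines(path)
  header_i <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 20 && all(tok[1:20] %in% PSSM_AA_ORDER) &&
        length(unique(tok[1:20])) == 20) {
      header_i <- i
      break
    }
  }
  if (is.na(header_i))
    abort("malformed PSSM: no amino-acid header line found")
  header <- strsplit(trimws(lines[header_i]), "\\s+")[[1]][1:20]
  rows <- list()
  residues <- character(0)
  for (i in seq(header_i + 1, length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(K\\s|Lambda|Standard|PSI|Gapped)", ln)) break
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 22 || is.na(suppressWarnings(as.integer(tok[1]))))
      abort(paste0("malformed PSSM row at line ", i))
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (any(is.na(vals)))
      abort(paste0("malformed PSSM row at line ", i))
    rows[[length(rows) + 1]] <- vals
    residues <- c(residues, tok[2])
  }
  if (length(rows) == 0) abort("PSSM contains no data rows")
  m <- do.call(rbind, rows)
  # reorder columns to the canonical order if the header differs
  m <- m[, match(PSSM_AA_ORDER, header), drop = FALSE]
  colnames(m) <- PSSM_AA_ORDER
  storage.mode(m) <- "integer"
  attr(m, "residues") <- residues
  m
}

# Convert profile scores to [0,1]: probabilities via 2^(-x/1000); the '*'
# sentinel (impossible transition/emission) maps to 0.
hmm_score_to_prob <- function(tok) {
  x <- suppressWarnings(as.numeric(tok))
  out <- pmin(pmax(2^(-x / 1000), 0), 1)
  out[tok == "*"] <- 0
  if (any(is.na(out))) abort("malformed profile score (not numeric or '*')")
  out
}

#' Parse a HMMER3 text profile into the n x 30 feature block
#'
#' Reads a HMMER3 `.hmm` profile and converts per-position scores to
#' `[0, 1]` probabilities with the `2^(-score/1000)` convention (`*`
#' entries map to 0). Column map, fixed: 1-20 match emissions in the
#' profile's alphabet order; 21-27 the seven state transitions
#' (m->m, m->i, m->d, i->m, i->i, d->m, d->d); 28-30 local diversity
#' summaries of the insert-emission distribution (mean, min, max of the
#' converted insert-emission probabilities).
#'
#' @param path HMMER3 profile file.
#' @return Numeric `n x 30` matrix with entries in `[0, 1]`.
#' @export
parse_hmm <- function(path) {
  if (!file.exists(path)) abort(paste0("HMM file not found: ", path))
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^HMMER3", lines[1]))
    abort("not a HMMER3 profile (missing HMMER3 header)")
  hmm_i <- grep("^HMM\\s", lines)[1]
  if (is.na(hmm_i)) abort("malformed HMMER3 profile: no HMM section")
  i <- hmm_i + 2  # skip the transition header line
  # optional COMPO block (three lines)
  if (grepl("^\\s*COMPO\\s", lines[i])) i <- i + 3
  rows <- list()
  while (i <= length(lines) && !grepl("^//", lines[i])) {
    tok_m <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    pos <- suppressWarnings(as.integer(tok_m[1]))
    if (is.na(pos) || length(tok_m) < 21)
      abort(paste0("malformed match-emission line at line ", i))
    match_p <- hmm_score_to_prob(tok_m[2:21])
    if (i + 2 > length(lines))
      abort(paste0("truncated HMMER3 profile at line ", i))
    tok_i <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(tok_i) < 20)
      abort(paste0("malformed insert-emission line at line ", i + 1))
    ins_p <- hmm_score_to_prob(tok_i[1:20])
    tok_t <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    if (length(tok_t) < 7)
      abort(paste0("malformed transition line at line ", i + 2))
    trans_p <- hmm_score_to_prob(tok_t[1:7])
    rows[[length(rows) + 1]] <-
      c(match_p, trans_p, mean(ins_p), min(ins_p), max(ins_p))
    i <- i + 3
  }
  if (length(rows) == 0) abort("HMMER3 profile contains no positions")
  m <- do.call(rbind, rows)
  colnames(m) <- c(paste0("m_", seq_len(20)),
                   c("t_mm", "t_mi", "t_md", "t_im", "t_ii", "t_dm", "t_dd"),
                   c("ins_mean", "ins_min", "ins_max"))
  m
}

#' Load a per-residue embedding matrix
#'
#' Embeddings are consumed, not computed: the expected file is a
#' whitespace/tab-separated numeric table of `n` rows and 1024 columns as
#' produced by an external protein language model export.
#'
#' @param path Embedding file.
#' @param n Expected row count (residues).
#' @param allow_missing When `TRUE` a missing file yields a zero matrix
#'   flagged with `attr(, "missing") = TRUE` instead of an error.
#' @return Numeric `n x 1024` matrix.
#' @export
load_embedding <- function(path, n, allow_missing = FALSE) {
  if (!file.exists(path)) {
    if (allow_missing) {
      m <- matrix(0, n, 1024)
      attr(m, "missing") <- TRUE
      return(m)
    }
    abort(paste0("embedding file not found: ", path))
  }
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != n || ncol(m) != 1024)
    abort(paste0("embedding shape mismatch: expected ", n,
                 " x 1024, found ", nrow(m), " x ", ncol(m)))
  m
}

#' Bundle normalized evolutionary profiles
#'
#' Applies the sigmoid normalization to raw PSSM log-odds and checks the
#' HMM block is already in `[0, 1]`, producing the 50-column evolutionary
#' feature block used by [build_graph()].
#'
#' @param pssm_raw Raw `n x 20` PSSM log-odds (from [parse_pssm()]).
#' @param hmm `n x 30` HMM feature block in `[0, 1]` (from [parse_hmm()]).
#' @param source_meta Optional list of tool/database provenance tags.
#' @return An object of class `profile_set` with elements `pssm`
#'   (normalized, strictly inside `(0,1)`), `hmm`, `source_meta`.
#' @export
profile_set <- function(pssm_raw, hmm, source_meta = list()) {
  pssm_raw <- as.matrix(pssm_raw)
  hmm <- as.matrix(hmm)
  if (ncol(pssm_raw) != 20) abort("pssm must have 20 columns")
  if (ncol(hmm) != 30) abort("hmm must have 30 columns")
  if (nrow(pssm_raw) != nrow(hmm))
    abort("pssm and hmm row counts differ")
  if (!all(is.finite(pssm_raw)) || !all(is.finite(hmm)))
    abort("profile matrices must be finite")
  if (any(hmm < 0 | hmm > 1)) abort("hmm entries must lie in [0, 1]")
  structure(list(pssm = sigmoid_normalize(pssm_raw), hmm = hmm,
                 source_meta = source_meta),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("<profile_set> n=", nrow(x$pssm), ", PSSM 20 + HMM 30 columns\n",
      sep = "")
  invisible(x)
}
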