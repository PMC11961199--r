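# Shared fixtures: all built in code, tiny sizes, fixed seeds. A few
# expensive generator outputs are memoized for reuse within the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

tiny_synth_config <- function(...) {
  synth_config(n_enzymes = 6, n_test = 3, residues_per_enzyme = 30,
               catalytic_per_enzyme = 3, n_classes = 2, seed = 11, ...)
}

small_dataset <- function() {
  memo("small_dataset", {
    synth_dataset(tiny_synth_config(), n = 6)
  })
}

small_graphs <- function() {
  memo("small_graphs", bundle_graphs(small_dataset()))
}

# hand-built 3-residue glycine chain with collinear Calphas at 0, 6, 12 A
toy_record <- function(ca = rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0)),
                       mask = NULL) {
  n <- nrow(ca)
  if (is.null(mask)) mask <- integer(n)
  atoms <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(
      res_index = i, name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = ca[i, 1] + c(-1.2, 0, 1.3, 1.9),
      y = ca[i, 2] + c(0.5, 0, 0.4, 1.4), z = ca[i, 3],
      b = 30, is_sidechain = FALSE)
  }))
  enzyme_record(id = "toy_A", sequence = strrep("G", n),
                residue_numbers = as.character(seq_len(n)),
                ca_coords = ca, atoms = atoms, catalytic_mask = mask)
}

toy_profiles <- function(n) {
  set.seed(99)
  profile_set(matrix(as.integer(round(rnorm(n * 20, 0, 2))), n, 20),
              matrix(runif(n * 30), n, 30))
}

# minimal fixed-width PDB writer for hand-crafted parser edge cases
pdb_lines <- function(serial, name, resname, chain, resno, x, y, z,
                      b = 30, element = substr(name, 1, 1),
                      record = "ATOM") {
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, chain, resno, x, y, z, 1, b,
          element)
}

write_toy_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# dense random symmetric binary adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(stats::rbinom(n * n, 1, p), n, n)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 0
  a
}
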