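# Small builders shared across tests, plus an independent brute-force
# oracle for intersection/consensus operations. The oracle works directly
# on raw target sets, never touching the target-matrix code path it checks.

make_study <- function(targets, study_id = "s", tf = "FKH1") {
  suppressWarnings(
    study_dataset(data.frame(gene = targets), study_id = study_id, tf = tf)
  )
}

make_studies <- function(sets, tf = "FKH1") {
  purrr::imap(sets, function(targets, id) make_study(targets, id, tf))
}

# Exhaustive per-gene enumeration: for each gene in any set, record the
# exact subset of studies containing it.
oracle_exclusive <- function(sets) {
  all_genes <- sort(unique(unlist(sets)))
  out <- list()
  for (g in all_genes) {
    members <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    key <- paste(members, collapse = "&")
    out[[key]] <- c(out[[key]], g)
  }
  out
}

oracle_k_of_n <- function(sets, k) {
  all_genes <- sort(unique(unlist(sets)))
  hits <- vapply(all_genes, function(g) {
    sum(vapply(sets, function(s) g %in% s, logical(1)))
  }, integer(1))
  all_genes[hits >= k]
}

oracle_hamming <- function(set_a, set_b, genes) {
  agree <- vapply(genes, function(g) (g %in% set_a) == (g %in% set_b), logical(1))
  sum(agree) / length(genes)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Random membership sets over a small universe, for property-style loops.
random_sets <- function(n_studies, genes, p = 0.4) {
  sets <- lapply(seq_len(n_studies), function(i) {
    genes[stats::runif(length(genes)) < p]
  })
  names(sets) <- paste0("s", seq_len(n_studies))
  sets
}
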