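# Shared fixture builders. Everything is generated in code; no binary files.

# Small deterministic matrix: `ng` genes x (4 groups x n) samples with
# group-specific log2 means given per gene as a ng x 4 matrix (CCD, NMC,
# ICD, NMI order). Returns list(matrix, meta).
tiny_cohort <- function(mu, n = 5, sigma = 0.3, seed = 1,
                        groups = c("CCD", "NMC", "ICD", "NMI")) {
  set.seed(seed)
  ng <- nrow(mu)
  ids <- unlist(lapply(groups, function(g) sprintf("%s_%d", g, seq_len(n))))
  meta <- sample_metadata(ids, rep(groups, each = n))
  vals <- matrix(0, ng, length(ids))
  for (gi in seq_along(groups)) {
    idx <- (gi - 1) * n + seq_len(n)
    vals[, idx] <- 2^(mu[, gi] + matrix(rnorm(ng * n, sd = sigma), ng, n))
  }
  m <- expression_matrix(vals, gene_ids = sprintf("g%03d", seq_len(ng)),
                         sample_ids = ids)
  list(matrix = m, meta = meta)
}

# Hand-built four-comparison tables for one gene universe, from a data.frame
# with columns gene_id and, per comparison c in names(specs):
# p_<c>, pass_<c> (logical is_deg & is_ci_disjoint), dir_<c>.
fake_tables <- function(df) {
  comps <- c("CCDvsNMC", "ICDvsNMI", "CCDvsICD", "NMCvsNMI")
  out <- lapply(comps, function(cc) {
    p <- df[[paste0("p_", cc)]]
    pass <- df[[paste0("pass_", cc)]]
    dirn <- df[[paste0("dir_", cc)]]
    if (is.null(dirn)) dirn <- ifelse(pass, "a_up", "none")
    data.frame(gene_id = df$gene_id, comparison = cc, test_used = "t_equal_var",
               p_value = p,
               lci_a = 0, hci_a = 0, lci_b = 0, hci_b = 0,
               is_deg = p <= 0.05, is_ci_disjoint = pass & p <= 0.05,
               direction = dirn, stringsAsFactors = FALSE)
  })
  names(out) <- comps
  out
}

# Brute-force exact two-sided rank-sum p-value by enumerating all
# assignments of the pooled observations to group a (no ties assumed).
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}
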