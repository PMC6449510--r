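# Shared fixture builders. Everything is generated in code at test time.

# minimal well-formed table with k rows and reported CUE values
tiny_dataset <- function(cue = c(0.2, 0.4, 0.6)) {
  n <- length(cue)
  data.frame(
    record_id = paste0("r", seq_len(n)), site_id = "s1",
    latitude = 10, longitude = 20, mat = 12, map = 800, ph = 6.5,
    cn_ratio = 12, pft = "forest", incubation_temp = 20,
    substrate_text = "glucose", substrate_category = "glucose",
    cue = cue, delta_mbc = NA_real_, delta_c_substrate = NA_real_,
    r_cumulative = NA_real_, resp_rate = NA_real_, duration = NA_real_,
    source_year = 2000, stringsAsFactors = FALSE)
}

# dataset with normal CUE per group: named means/sds, n per group
grouped_dataset <- function(means, sds, n_per_group, seed = 1,
                            column = "substrate_category") {
  set.seed(seed)
  rows <- lapply(names(means), function(g) {
    ds <- tiny_dataset(pmin(pmax(
      rnorm(n_per_group, means[[g]], sds[[g]]), 0.002), 0.993))
    ds$record_id <- paste0(g, "_", seq_len(n_per_group))
    ds[[column]] <- g
    ds
  })
  do.call(rbind, rows)
}

# brute-force check that a compact letter display is consistent with a
# pairwise p-value matrix: significant pairs share no letter, and
# non-significant pairs share at least one
cld_consistent <- function(letters_disp, p_matrix, alpha = 0.05) {
  groups <- names(letters_disp)
  for (a in groups) for (b in groups) {
    if (a >= b) next
    shared <- length(intersect(strsplit(letters_disp[[a]], "")[[1]],
                               strsplit(letters_disp[[b]], "")[[1]])) > 0
    if (p_matrix[a, b] < alpha && shared) return(FALSE)
    if (p_matrix[a, b] >= alpha && !shared) return(FALSE)
  }
  TRUE
}

# Monte-Carlo standard error of a pooled posterior mean via batch means
# computed per chain (20 batches each), combined across chains
pooled_mcse <- function(fit, parameter) {
  per_chain_var <- vapply(fit$chains, function(ch) {
    x <- ch$samples[-seq_len(ch$burn_in), parameter]
    nb <- 20L
    bsize <- floor(length(x) / nb)
    bm <- vapply(seq_len(nb), function(b)
      mean(x[((b - 1) * bsize + 1):(b * bsize)]), numeric(1))
    stats::var(bm) / nb              # var of this chain's mean
  }, numeric(1))
  sqrt(sum(per_chain_var)) / length(fit$chains)
}
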