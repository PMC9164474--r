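# Fixture builders shared by the test files. Everything is generated in
# code; no data files.

# A window with given residues at signed positions (default alanine
# elsewhere, serine at the phosphoacceptor).
make_window <- function(..., center = "S") {
  at <- list(...)
  res <- rep("A", 13)
  res[7] <- center
  for (pos in names(at)) {
    res[as.integer(pos) + 7] <- at[[pos]]
  }
  paste(res, collapse = "")
}

# One-row phosphosite record. Replicates are ratio + c(-spread, 0, +spread),
# so the mean equals `ratios` exactly and the replicate SD is spread*1.
make_site <- function(id, window, ratios, gene = paste0("G_", id),
                      spread = 0.01, reps = NULL) {
  df <- data.frame(
    site_id = id, gene_symbol = gene,
    residue = substr(window, 7, 7), position = 100L, window = window,
    stringsAsFactors = FALSE
  )
  for (t in seq_along(kinbayes:::TIMEPOINTS)) {
    tp <- kinbayes:::TIMEPOINTS[t]
    df[[paste0("ratio_", tp)]] <- ratios[t]
    r <- if (is.null(reps)) ratios[t] + c(-spread, 0, spread) else reps[[t]]
    for (j in 1:3) df[[paste0("rep", j, "_", tp)]] <- r[j]
  }
  df
}

make_sites <- function(...) do.call(rbind, list(...))

# A small registry with a ring neighbor map.
make_test_registry <- function(symbols, families = NULL) {
  n <- length(symbols)
  if (is.null(families)) families <- rep("AGC", n)
  list(
    kinases = data.frame(symbol = symbols, family = families,
                         stringsAsFactors = FALSE),
    neighbor_map = stats::setNames(symbols[c(seq_len(n)[-1], 1)], symbols)
  )
}

# Substrate records that all survive the localization filter.
make_substrates <- function(kinase, windows) {
  data.frame(kinase = kinase, window = windows,
             localization_probability = 0.95,
             has_site_determining_ions = TRUE, stringsAsFactors = FALSE)
}

# A deterministic tiny evidence bundle over three kinases, used by the
# pipeline-level tests. KA is serine-directed with a proline-at-+1 motif; KB
# is serine-directed without it; KC is a tyrosine kinase.
tiny_bundle <- function() {
  reg <- make_test_registry(c("KA", "KB", "KC"),
                            families = c("CMGC", "AGC", "TK"))
  wa <- replicate(30, make_window("1" = "P", "-3" = sample(c("A", "G", "L"), 1)))
  wb <- replicate(30, make_window("-3" = "R", "-2" = "R"))
  wc <- replicate(30, make_window("2" = "E", center = "Y"))
  profs <- rbind(KA = c(0.7, 0.2, 0.1), KB = c(0.1, 0.2, 0.7),
                 KC = c(0.3, 0.4, 0.3))
  colnames(profs) <- paste0("frac", 1:3)
  sprofs <- rbind(G1 = c(0.65, 0.25, 0.10), G2 = c(0.7, 0.2, 0.1),
                  G3 = c(0.1, 0.3, 0.6))
  colnames(sprofs) <- paste0("frac", 1:3)
  evidence_bundle(
    registry = reg,
    transcript = c(KA = 10, KB = 8, KC = 6),
    protein_a = c(KA = 9, KB = 7, KC = 5),
    protein_b = c(KA = 9, KB = 7),
    substrates = rbind(make_substrates("KA", wa), make_substrates("KB", wb),
                       make_substrates("KC", wc)),
    kinase_profiles = profs,
    site_profiles = sprofs,
    activity = c(KA = "increase", KB = "decrease", KC = "none"),
    background_windows = replicate(60, paste(
      c(sample(kinbayes:::AA_STANDARD, 6, TRUE), "S",
        sample(kinbayes:::AA_STANDARD, 6, TRUE)), collapse = ""))
  )
}
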