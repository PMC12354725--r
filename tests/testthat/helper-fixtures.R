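# Shared fixture builders and brute-force oracles.

# minimal canonical records with controllable condition labels
tiny_records <- function(n, metal = rep("Pd", n), cycle = rep(0L, n),
                         yield = rep(80, n), rtype = rep("suzuki_miyaura", n),
                         support = rep("Au", n), prep = rep("thermal", n)) {
  tibble::tibble(
    reaction_id = sprintf("r%03d", seq_len(n)),
    reaction_type = rtype, reuse_cycle = as.integer(cycle),
    yield_pct = yield, nucleophile_step_code = 1L, intramolecular = FALSE,
    split_label = "unassigned",
    c_1 = paste0("SA", metal), c_2 = support, c_3 = "mesh", c_4 = metal,
    c_5 = prep, c_6 = "piranha", c_7 = "gen1", c_8 = rtype, c_9 = "GC",
    catalyst_id = paste0("cat_", metal, "_1"),
    catalyst_qty_s1 = 10, catalyst_qty_s2 = NA_real_,
    catalyst_unit = "µg", catalyst_step = "1",
    electrophile_id = "el_1", electrophile_qty_s1 = 1,
    electrophile_qty_s2 = NA_real_, electrophile_unit = "mmol",
    electrophile_step = "1",
    nucleophile_id = "nu_1", nucleophile_qty_s1 = 1,
    nucleophile_qty_s2 = NA_real_, nucleophile_unit = "mmol",
    nucleophile_step = "1",
    solvent_id = "sol_1", solvent_qty_s1 = 2, solvent_qty_s2 = NA_real_,
    solvent_unit = "mL", solvent_step = "1",
    base_id = "base_1", base_qty_s1 = 1, base_qty_s2 = NA_real_,
    base_unit = "mmol", base_step = "1"
  )
}

# a random feature table with a given number of perturbation-style columns
random_features <- function(n, k, seed = 1, ref_mean = 79, ref_sd = 10) {
  set.seed(seed)
  out <- tibble::tibble(
    reaction_id = sprintf("r%03d", seq_len(n)),
    yield_ref = rnorm(n, ref_mean, ref_sd)
  )
  for (j in seq_len(k)) out[[paste0("t", j)]] <- rnorm(n, sd = 2)
  out
}

# brute-force AUC: all positive/negative pairs, ties count one half
auc_brute <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force per-group centering: double loop over records
delta_brute <- function(raw, groups) {
  out <- numeric(length(raw))
  for (i in seq_along(raw)) {
    members <- which(groups == groups[i])
    out[i] <- raw[i] - mean(raw[members])
  }
  out
}
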