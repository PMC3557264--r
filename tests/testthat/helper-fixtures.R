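# small deterministic table: 5 languages, 3 features, 2 families
toy_table <- function() {
  v <- rbind(c("a", "a", "b", "b", NA),
             c("x", "y", "x", NA,  "y"),
             c("1", "1", "1", "2", "2"))
  TypologyTable(v,
                languages = data.frame(language_id = paste0("l", 1:5),
                                       family = c("F1", "F1", "F2", "F2", "F2"),
                                       genus = c("g1", "g1", "g2", "g2", "g3"),
                                       area = c("A", "A", "A", "B", "B")),
                features = data.frame(feature_id = 1:3))
}

# random table with family/genus/area structure but i.i.d. feature values
random_table <- function(n_lang = 6, n_feat = 4, k = 3, miss = 0.15,
                         n_fam = 2, seed = 1) {
  set.seed(seed)
  v <- matrix(sample(letters[1:k], n_lang * n_feat, replace = TRUE),
              n_feat, n_lang)
  v[matrix(runif(n_feat * n_lang) < miss, n_feat, n_lang)] <- NA
  fam <- paste0("F", rep_len(seq_len(n_fam), n_lang))
  TypologyTable(v,
                languages = data.frame(language_id = paste0("l", seq_len(n_lang)),
                                       family = fam,
                                       genus = paste0(fam, ".g", rep_len(1:2, n_lang)),
                                       area = paste0("A", rep_len(1:2, n_lang))),
                features = data.frame(feature_id = seq_len(n_feat)))
}

# table with explicit per-language metadata and value matrix
make_table <- function(values, family, genus = family, area = "A1") {
  n <- ncol(values)
  TypologyTable(values,
                languages = data.frame(language_id = paste0("l", seq_len(n)),
                                       family = rep_len(family, n),
                                       genus = rep_len(genus, n),
                                       area = rep_len(area, n)),
                features = data.frame(feature_id = seq_len(nrow(values))))
}
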