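# Hand-written zone oracle for all 25 (unseeded, seeded) observation pairs
# (4 outcomes + missing arm, both arms). Independent of classify_pair().

truth_table_oracle <- function() {
  levels <- c("clear", "crystals", "shower", "precipitate", NA)
  tab <- expand.grid(unseeded = levels, seeded = levels,
                     stringsAsFactors = FALSE)
  zone <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    u <- tab$unseeded[i]
    s <- tab$seeded[i]
    zone[i] <-
      if (is.na(u)) {
        "unknown"                             # unseeded arm missing
      } else if (u %in% c("crystals", "shower")) {
        if (!is.na(s) && s == "clear") "inconsistent" else "nucleation"
      } else if (u == "precipitate") {
        "precipitation"
      } else {                                # u == "clear"
        if (is.na(s)) "unknown"
        else if (s %in% c("crystals", "shower")) "metastable"
        else if (s == "precipitate") "precipitation"
        else "undersaturated"
      }
  }
  tab$zone <- zone
  tab
}
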