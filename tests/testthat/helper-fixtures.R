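# Shared fixtures: small simulation configs and a proteinGroups TSV writer.

small_cfg <- function(seed = 42, ...) {
  args <- list(n_genes = 300, n_proteins = 100,
               conditions = c("mutA", "mutB", "mutC"),
               go_terms = 25, seed = seed)
  args[names(list(...))] <- list(...)
  args$n_proteins <- min(args$n_proteins, args$n_genes)
  do.call(sim_config, args)
}

# write a minimal MaxQuant-dialect proteinGroups file and return its path
write_pg_fixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "proteinGroups.txt")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NaN")
  path
}

pg_fixture_df <- function() {
  data.frame(
    `Protein IDs` = c("P1", "P2", "P3", "REV__P4", "CON__P5"),
    `Ratio H/L normalized wt_1` = c(1.0, 2.0, 0.5, 1.1, 0.9),
    `Ratio H/L normalized wt_2` = c(1.1, NA, 0.6, 1.0, 1.0),
    `Ratio H/L normalized mutA_1` = c(0.5, 1.0, 0.25, 1.2, 1.1),
    `Ratio H/L normalized mutA_2` = c(0.55, 1.0, NA, 0.8, 0.7),
    `Intensity H` = c(9e6, 8e6, 7e6, 1e6, 1e6),
    `Intensity L` = c(1e6, 2e6, 3e6, 1e6, 1e6),
    Reverse = c("", "", "", "+", ""),
    `Potential contaminant` = c("", "", "", "", "+"),
    check.names = FALSE, stringsAsFactors = FALSE)
}

# tiny diamond DAG: d -> {b, c} -> a
diamond_dag <- function() {
  go_dag(data.frame(child = c("d", "d", "b", "c"),
                    parent = c("b", "c", "a", "a"),
                    stringsAsFactors = FALSE))
}
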