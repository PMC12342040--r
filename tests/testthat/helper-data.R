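# Hand-built miniature datasets used across the suite. Everything is
# generated in code; nothing is read from stored fixtures.

tiny_counts <- function() {
  m <- matrix(c(3, 1, 0, 5,
                4, 0, 2, 1,
                0, 6, 1, 2,
                2, 2, 2, 2,
                1, 0, 0, 3), nrow = 5, byrow = TRUE)
  dimnames(m) <- list(paste0("ASV_", 1:5),
                      c("Low_T1_R1", "Low_T1_R2", "Low_T2_R1", "Low_T2_R2"))
  storage.mode(m) <- "integer"
  m
}

tiny_taxonomy <- function(ids = paste0("ASV_", 1:5)) {
  data.frame(domain = "Bacteria", phylum = "Proteobacteria",
             class = "Gammaproteobacteria", order = "Burkholderiales",
             family = "Rhodocyclaceae",
             genus = c("Thauera", "Thauera", "Zoogloea", "Tepidicella",
                       "unassigned")[seq_along(ids)],
             species = "unassigned", row.names = ids,
             stringsAsFactors = FALSE)
}

tiny_metadata <- function(samples = c("Low_T1_R1", "Low_T1_R2",
                                      "Low_T2_R1", "Low_T2_R2")) {
  data.frame(group = "Low", temperature = 15,
             timepoint = rep(1:2, each = 2), replicate = rep(1:2, 2),
             phase = "DNA-enrichment", row.names = samples,
             stringsAsFactors = FALSE)
}

tiny_dataset <- function() {
  nc_dataset(tiny_counts(), tiny_taxonomy(), tiny_metadata())
}

# small simulation config used where the full study-scale design would be
# needlessly slow
small_cfg <- function(source_alpha = 3.5, ...) {
  simulation_config(n_taxa = 120, depth_range = c(4000, 12000),
                    local_community_size = 4000, cdna_timepoints = 0,
                    source_alpha = source_alpha, group_effect = 0, ...)
}

# write a 3-taxon x 2-sample TSV fixture set and return the paths
write_mini_fixture <- function(dir, tree = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- matrix(c(5L, 2L, 0L, 7L, 1L, 3L), nrow = 3,
                   dimnames = list(c("A1", "A2", "A3"), c("S1", "S2")))
  ab <- data.frame(feature_id = rownames(counts), counts, check.names = FALSE)
  write.table(ab, file.path(dir, "abundance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tx <- data.frame(feature_id = rownames(counts),
                   tiny_taxonomy(rownames(counts)), check.names = FALSE)
  write.table(tx, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = c("S1", "S2"), group = "Low",
                   temperature = 15, timepoint = 1:2, replicate = 1,
                   phase = "DNA-enrichment")
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (tree)
    writeLines("((A1:0.5,A2:0.5):0.5,A3:1.0);", file.path(dir, "tree.nwk"))
  dir
}

# star tree over the given tips with unit branch lengths
star_tree <- function(tips) {
  tree <- ape::read.tree(text = paste0("(",
    paste0(tips, ":1", collapse = ","), ");"))
  tree
}
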