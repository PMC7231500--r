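# in-code fixtures shared across tests

# tiny two-sample table with one shared taxon
toy_table <- function() {
  abundance_table(rbind(s1 = c(a = 4, b = 0, c = 1),
                        s2 = c(a = 1, b = 1, c = 0)))
}

# random abundance table for property-style loops
random_table <- function(n_samples = 4, n_taxa = 8, size = 60) {
  m <- t(vapply(seq_len(n_samples),
                function(i) as.numeric(rmultinom(1, size, runif(n_taxa))),
                numeric(n_taxa)))
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      paste0("t", seq_len(n_taxa)))
  # guard against all-zero rows at tiny sizes
  m[rowSums(m) == 0, 1] <- 1
  abundance_table(m)
}

# the Rumerlo ski slope sample before the foraminifer exclusion
rumerlo_ski_raw <- function() {
  tab <- cassian_new4()
  x <- tab["Rumerlo ski slope", , drop = TRUE]
  x <- x[x > 0]
  m <- matrix(c(x, `Pragsoconulus robustus` = 11), nrow = 1,
              dimnames = list("Rumerlo ski slope",
                              c(names(x), "Pragsoconulus robustus")))
  abundance_table(m)
}

# the published two-group depth split of the eight Cassian samples
cassian_depth_split <- function(k = 2) {
  md <- cassian_metadata()
  depth_groups(setNames(md$depth_rank, md$sample_id), k)
}
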