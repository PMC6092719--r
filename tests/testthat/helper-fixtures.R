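# Shared in-code fixtures.

# 4-accession toy distance matrix used throughout the worked examples:
# d(1,2)=0.1 d(1,3)=0.5 d(1,4)=0.6 d(2,3)=0.4 d(2,4)=0.7 d(3,4)=0.2
toy_dmat <- function() {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.1; m[1, 3] <- 0.5; m[1, 4] <- 0.6
  m[2, 3] <- 0.4; m[2, 4] <- 0.7; m[3, 4] <- 0.2
  distance_matrix(m + t(m), accessions = paste0("acc", 1:4))
}

toy_dataset <- function() core_dataset(distances = toy_dmat())

# tiny genotype matrix from explicit frequency rows (one or more loci)
make_geno <- function(rows, n_alleles) {
  freq <- do.call(rbind, rows)
  cn <- unlist(lapply(seq_along(n_alleles), function(l) {
    sprintf("loc%d.a%d", l, seq_len(n_alleles[l]))
  }))
  colnames(freq) <- cn
  genotype_matrix(freq, accessions = sprintf("g%02d", seq_len(nrow(freq))))
}

ene_config <- function() objective_config(list(objective("E-NE")))

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
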