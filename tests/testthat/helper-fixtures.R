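# Small in-code fixture builders shared across test files.

make_sites <- function(pos, n_meth, n_unmeth, chrom = "chr1", strand = "+",
                       context = "CG", ...) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 context = context, n_meth = as.integer(n_meth),
                 n_unmeth = as.integer(n_unmeth), ...)
}

make_gene <- function(gene_id, exon_starts, exon_ends, chrom = "chr1",
                      strand = "+") {
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = as.integer(exon_starts),
                 end = as.integer(exon_ends),
                 exon_rank = seq_along(exon_starts))
}

# random valid cytosine table for round-trip tests
random_cx <- function(n, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(50000, n))
  tibble::tibble(
    chrom = "chr1", pos = pos,
    strand = sample(c("+", "-"), n, replace = TRUE),
    context = sample(c("CG", "CA", "CT", "CC"), n, replace = TRUE),
    n_meth = rpois(n, 5), n_unmeth = rpois(n, 5)
  )
}

# small multi-sample count table at one feature for DM-calling tests
pair_counts <- function(feature_id, a1, b1, a2, b2) {
  # each of a1.. is c(n_meth, n_unmeth)
  tibble::tibble(
    feature_id = feature_id,
    tissue = rep(c("A", "B"), each = 2),
    replicate = c(1L, 2L, 1L, 2L),
    n_meth = c(a1[1], a2[1], b1[1], b2[1]),
    n_unmeth = c(a1[2], a2[2], b1[2], b2[2])
  )
}
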