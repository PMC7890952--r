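# Small in-code fixtures shared by the unit tests.

tiny_expr <- function(genes = c("g1", "g2", "g3"),
                      samples = c("s1", "s2"),
                      values = seq_len(length(genes) * length(samples))) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

write_tsv_lines <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext,
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# A hand-checkable 4-file input set: 3 coding + 1 noncoding gene,
# 3 miRNAs, fully harmonizable.
tiny_inputs <- function() {
  cerna <- tiny_expr(c("A", "B", "C", "L"), c("s1", "s2", "s3"),
                     values = c(5, 3, 8, 2, 6, 4, 9, 1, 7, 5, 10, 3))
  mirna <- tiny_expr(c("m1", "m2", "m3"), c("s1", "s2", "s3"),
                     values = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  inter <- data.frame(
    mirna = c("m1", "m1", "m2", "m2", "m3"),
    target = c("A", "B", "A", "B", "C"), stringsAsFactors = FALSE)
  ann <- data.frame(symbol = c("A", "B", "C", "L"),
                    biotype = c("protein_coding", "protein_coding",
                                "protein_coding", "lincRNA"),
                    stringsAsFactors = FALSE)
  list(cerna_expr = cerna, mirna_expr = mirna, interactions = inter,
       annotation = ann)
}
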