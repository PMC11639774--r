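# Fixtures built in code: tiny quant tables and a silhouette helper.

# balanced quant table: 2 colors x 2 varieties x n_rep, one feature row per
# entry of `rows` (a named list of numeric vectors in sample order)
make_quant <- function(rows, colors = c("white", "purple"), n_var = 2,
                       n_rep = 3) {
  meta <- do.call(rbind, lapply(colors, function(cl) {
    do.call(rbind, lapply(seq_len(n_var), function(v) {
      data.frame(sample_id = sprintf("%s%d_r%d", cl, v, seq_len(n_rep)),
                 variety = sprintf("%s%d", cl, v),
                 color = cl, replicate = seq_len(n_rep))
    }))
  }))
  vals <- do.call(rbind, rows)
  rownames(vals) <- names(rows)
  colnames(vals) <- meta$sample_id
  quant_table(vals, meta)
}

# mean silhouette width of a 2-group labelling over rows of x
mean_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(dist(x))
  widths <- vapply(seq_len(nrow(x)), function(i) {
    same <- labels == labels[i]
    a <- mean(d[i, same & seq_len(nrow(x)) != i])
    b <- min(vapply(unique(labels[!same]), function(g)
      mean(d[i, labels == g]), 0.0))
    (b - a) / max(a, b)
  }, 0.0)
  mean(widths)
}
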