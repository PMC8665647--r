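# internal helpers

# evaluate `code` under set.seed(seed) without disturbing the caller's RNG
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a child seed below 2^31 from a master seed + stream label
derive_seed <- function(seed, index, stream = 0L) {
  (as.numeric(seed) * 48271 + index * 9973 + stream * 101) %% 2147483629
}

# long (sample x analyte, value) tibble -> numeric matrix analytes x samples
long_to_matrix <- function(df, value_col = "value") {
  wide <- tidyr::pivot_wider(
    df[, c("sample", "analyte", value_col)],
    names_from = "sample", values_from = dplyr::all_of(value_col)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$analyte
  m
}

matrix_to_long <- function(m, value_col = "value") {
  df <- tibble(
    analyte = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  names(df)[names(df) == "value"] <- value_col
  df
}
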