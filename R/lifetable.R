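#' Read and write background life tables
#'
#' Life tables are CSV files with columns `sex` (`male`/`female`), `age`
#' (integer, must cover 0..39) and `q` (annual probability of death).
#' Internally a life table is a `[2 sex, 40 age]` numeric matrix.
#'
#' @param path CSV path.
#' @return `read_life_table()` returns the `[2, 40]` matrix;
#'   `write_life_table()` writes one and returns the path invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", "q")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed life table ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  life_table_matrix(df)
}

life_table_matrix <- function(df) {
  q <- matrix(NA_real_, 2L, N_AGES, dimnames = list(SEXES, 0:(N_AGES - 1L)))
  s <- sex_index(df$sex)
  keep <- df$age >= 0 & df$age < N_AGES
  q[cbind(s[keep], df$age[keep] + 1L)] <- df$q[keep]
  if (anyNA(q)) stop("life table must provide q for both sexes at ages 0..39")
  if (any(q < 0 | q >= 1)) stop("life-table q must lie in [0, 1)")
  q
}

#' @rdname read_life_table
#' @param life_table a `[2, 40]` life-table matrix.
#' @export
write_life_table <- function(life_table, path) {
  q <- as_life_table_matrix(life_table)
  df <- data.frame(sex = rep(SEXES, each = N_AGES),
                   age = rep(0:(N_AGES - 1L), 2L),
                   q = c(q[1, ], q[2, ]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
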