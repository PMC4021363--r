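# Internal helpers shared across modules.

# Columns in participant tables that are metadata, never analysed as variables.
META_COLS <- c("participant_id", "wave")
ENERGY_COL <- "energy_kj"

# Extract the numeric variable block of a participant table as a matrix,
# keeping participant ids as rownames when present.
table_matrix <- function(data, cols = NULL, drop_energy = TRUE) {
  stopifnot(is.data.frame(data))
  drop <- intersect(META_COLS, names(data))
  if (drop_energy) drop <- c(drop, intersect(ENERGY_COL, names(data)))
  vars <- setdiff(names(data), drop)
  if (!is.null(cols)) {
    missing <- setdiff(cols, vars)
    if (length(missing) > 0) {
      abort(paste0("missing required columns: ", paste(missing, collapse = ", ")))
    }
    vars <- cols
  }
  m <- as.matrix(as.data.frame(data)[vars])
  if (!is.numeric(m)) abort("non-numeric values in variable columns")
  if ("participant_id" %in% names(data)) {
    rownames(m) <- as.character(data$participant_id)
  }
  m
}

# Run code with a temporary RNG state when a seed is supplied; otherwise use
# the current RNG stream untouched.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

check_aligned_ids <- function(a, b, what = "tables") {
  ida <- a$participant_id
  idb <- b$participant_id
  if (is.null(ida) || is.null(idb)) return(invisible(TRUE))
  if (length(ida) != length(idb) || !all(as.character(ida) == as.character(idb))) {
    abort(paste0("participant ids of ", what, " are not aligned"))
  }
  invisible(TRUE)
}

# Sample standard deviation column-wise (n - 1 convention, used throughout).
col_sds <- function(m) apply(m, 2, sd)

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# All permutations of 1..n (n small) for factor matching diagnostics.
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}
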