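# Internal helpers shared across modules.

CHANNELS <- c("INSL5", "PYY", "GLP1")

CATEGORY_LEVELS <- c("single_INSL5", "single_PYY", "single_GLP1",
                     "double_INSL5_PYY", "double_INSL5_GLP1", "double_PYY_GLP1",
                     "triple", "indeterminate", "excluded")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == round(x)

# Run `expr` under a temporary RNG state seeded with `seed`; NULL leaves the
# global stream untouched.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# (z, y, x) 0-based voxel indices <-> 1-based column-major linear index for an
# array of dim (nz, ny, nx). First dim (z) varies fastest.
zyx_to_linear <- function(z, y, x, dims) {
  z + dims[1L] * (y + dims[2L] * x) + 1L
}

linear_to_zyx <- function(idx, dims) {
  i0 <- idx - 1L
  z <- i0 %% dims[1L]
  y <- (i0 %/% dims[1L]) %% dims[2L]
  x <- i0 %/% (dims[1L] * dims[2L])
  cbind(z = z, y = y, x = x)
}

# Physical voxel-centre coordinate (nm) of a 0-based index along one axis.
index_to_nm <- function(idx0, voxel_nm) idx0 * voxel_nm
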