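# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps^0.5) stop("cannot normalize a near-zero vector")
  v / n
}

# acute angle between two undirected axes, in [0, pi/2]
axis_angle <- function(a, b) {
  ca <- abs(sum(unitize(a) * unitize(b)))
  acos(min(1, max(-1, ca)))
}

# angle between two directed vectors, in [0, pi]
vec_angle <- function(a, b) {
  ca <- sum(unitize(a) * unitize(b))
  acos(min(1, max(-1, ca)))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# FNV-1a hash of an R object's deparsed form; provenance stamp for outputs
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor the byte into the low 16 bits (keeps operands within integer range)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    h <- ((lo * 16777619) %% 4294967296 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# derive a per-participant sub-seed below 2^31 so adding participants never
# perturbs earlier ones
participant_seed <- function(master_seed, participant) {
  (as.integer(master_seed) + participant * 10007L) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
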