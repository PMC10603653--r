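# Deterministic string hashing and counter-based pseudo-normals for the
# mock encoder. All arithmetic is exact in doubles (every intermediate
# stays below 2^53), so results are bit-identical across platforms and
# processes and independent of R's global RNG.

MOD32 <- 4294967296  # 2^32

# 32-bit multiply mod 2^32 without precision loss: split a into 16-bit
# halves so each product stays below 2^49.
mul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% MOD32
}

# bitwise XOR on 32-bit values carried as doubles
xor32 <- function(a, b) {
  alo <- a %% 65536; ahi <- (a - alo) / 65536
  blo <- b %% 65536; bhi <- (b - blo) / 65536
  bitwXor(as.integer(ahi), as.integer(bhi)) * 65536 +
    bitwXor(as.integer(alo), as.integer(blo))
}

# FNV-1a over a byte vector, optionally chained from a previous state
fnv1a <- function(bytes, state = 2166136261) {
  h <- state
  for (b in bytes) h <- mul32(xor32(h, b), 16777619)
  h
}

hashString <- function(s, seed = 0L) {
  bytes <- utf8ToInt(enc2utf8(s)) %% 256
  h <- fnv1a(c(seed %% 256, (seed %/% 256) %% 256,
               (seed %/% 65536) %% 256, (seed %/% 16777216) %% 256))
  fnv1a(bytes, state = h)
}

# splitmix-style counter stream: uniform in (0,1) for counters 1..n
hashUniforms <- function(h, n, salt = 0) {
  u <- numeric(n)
  for (j in seq_len(n)) {
    x <- (h + mul32(j + salt, 2654435761)) %% MOD32
    x <- mul32(xor32(x, x %/% 65536), 2246822519)
    x <- mul32(xor32(x, x %/% 8192), 3266489917)
    x <- xor32(x, x %/% 65536)
    u[j] <- (x + 0.5) / MOD32
  }
  u
}

# reproducible standard normals for a string under a given seed/salt
hashNormals <- function(s, dim, seed = 0L, salt = 0) {
  stats::qnorm(hashUniforms(hashString(s, seed), dim, salt))
}
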