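# internal helpers shared by the repeat finders and the simulator

# map a DNA character string to integer codes A=0 C=1 G=2 T=3, NA otherwise
.baseCodes <- function(s) {
  v <- utf8ToInt(s)
  code <- rep(NA_integer_, length(v))
  code[v == 65L] <- 0L  # A
  code[v == 67L] <- 1L  # C
  code[v == 71L] <- 2L  # G
  code[v == 84L] <- 3L  # T
  code
}

# exact numeric hash of every k-mer (base-4 polynomial); NA where the k-mer
# contains a non-ACGT letter. Exact for k <= 26 (4^26 < 2^53).
.kmerHash <- function(s, k) {
  code <- .baseCodes(s)
  n <- length(code)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  h <- numeric(m)
  bad <- logical(m)
  pow <- 4^(0:(k - 1L))
  for (j in seq_len(k)) {
    cj <- code[j:(m + j - 1L)]
    bad <- bad | is.na(cj)
    cj[is.na(cj)] <- 0L
    h <- h + cj * pow[j]
  }
  h[bad] <- NA_real_
  h
}

# X-drop extension of a direct-repeat seed along one diagonal.
# raw: raw bytes of the sequence; [s,e] the seed in the first copy; d the
# diagonal offset (second copy at +d). Returns the extended first-copy
# interval maximizing the match(+1)/mismatch(-1) score.
.extendDiagonal <- function(raw, s, e, d, xdrop = 20L) {
  n <- length(raw)
  # left extension
  score <- 0L; best <- 0L; bs <- s
  i <- s - 1L
  while (i >= 1L && score > best - xdrop) {
    score <- score + (if (raw[i] == raw[i + d]) 1L else -1L)
    if (score > best) { best <- score; bs <- i }
    i <- i - 1L
  }
  # right extension; the first copy must not run into the second
  score <- 0L; best <- 0L; be <- e
  i <- e + 1L
  while (i + d <= n && i < s + d && score > best - xdrop) {
    score <- score + (if (raw[i] == raw[i + d]) 1L else -1L)
    if (score > best) { best <- score; be <- i }
    i <- i + 1L
  }
  c(bs, be)
}

# X-drop extension of an inverted-repeat seed along one anti-diagonal c:
# position p in arm1 pairs with position c - p in arm2, which must carry
# the complementary base. [s,e] is the seed interval in arm1.
.extendAntiDiagonal <- function(raw, s, e, cdiag, xdrop = 20L) {
  n <- length(raw)
  comp <- .compRawTable()
  # outward (arm1 start decreases, arm2 end increases)
  score <- 0L; best <- 0L; bs <- s
  i <- s - 1L
  while (i >= 1L && cdiag - i <= n && score > best - xdrop) {
    score <- score +
      (if (comp[as.integer(raw[cdiag - i]) + 1L] == raw[i]) 1L else -1L)
    if (score > best) { best <- score; bs <- i }
    i <- i - 1L
  }
  # inward (arm1 end increases towards the spacer); arms must not cross
  score <- 0L; best <- 0L; be <- e
  i <- e + 1L
  while (2L * i < cdiag && score > best - xdrop) {
    score <- score +
      (if (comp[as.integer(raw[cdiag - i]) + 1L] == raw[i]) 1L else -1L)
    if (score > best) { best <- score; be <- i }
    i <- i + 1L
  }
  c(bs, be)
}

.compRawTable <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      t0 <- as.raw(0:255)
      t0[utf8ToInt("A") + 1L] <- charToRaw("T")
      t0[utf8ToInt("T") + 1L] <- charToRaw("A")
      t0[utf8ToInt("C") + 1L] <- charToRaw("G")
      t0[utf8ToInt("G") + 1L] <- charToRaw("C")
      tbl <<- t0
    }
    tbl
  }
})

# deterministic sub-seed for an independent random substream
.substream <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483647)
}

# random i.i.d. DNA string at a given GC fraction, as a character vector
# of single bases
.randBases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}
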