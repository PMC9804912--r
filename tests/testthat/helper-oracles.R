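# Independent oracles and small structure builders used across the suite.

# Brute-force connected components by flood fill over a distance matrix.
brute_components <- function(d, cutoff) {
  n <- nrow(d)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(d[v, ] <= cutoff & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Hand rank formula for the Kruskal-Wallis H with tie correction.
kw_oracle <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H0 <- 12 / (N * (N + 1)) *
    sum(tapply(seq_len(N), idx, function(ii) {
      length(ii) * (mean(r[ii]) - (N + 1) / 2)^2
    }))
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C == 0) return(0)
  H0 / C
}

# Lazy-quantifier regex oracle for the C2H2 consensus, stepping
# non-overlapping from the left.
c2h2_oracle <- function(seq) {
  pat <- "C.{2,4}?C.{3}[LIVMFYWC].{8}H.{3,5}?H"
  out <- data.frame(start = integer(), end = integer())
  offset <- 0L
  rest <- seq
  repeat {
    m <- regexpr(pat, rest, perl = TRUE)
    if (m == -1L) break
    st <- offset + as.integer(m)
    en <- st + attr(m, "match.length") - 1L
    out <- rbind(out, data.frame(start = st, end = en))
    offset <- en
    rest <- substr(seq, en + 1L, nchar(seq))
    if (nchar(rest) == 0L) break
  }
  out
}

# One residue's atom rows for hand-built structures.
res_block <- function(resno, aa, fun = NULL, ca = NULL, cb = NULL,
                      fun_name = NULL) {
  primary <- c(H = "NE2", C = "SG", D = "OD1", E = "OE1", S = "OG")
  rows <- list()
  if (!is.null(fun)) {
    nm <- fun_name
    if (is.null(nm)) nm <- primary[[aa]]
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, x = fun[1], y = fun[2], z = fun[3],
      resno = resno, aa = aa, chain = "A")
  }
  if (is.null(ca)) ca <- (if (is.null(fun)) c(0, 0, 0) else fun) + c(1.5, 0, 0)
  if (!is.null(cb))
    rows[[length(rows) + 1L]] <- data.frame(
      name = "CB", x = cb[1], y = cb[2], z = cb[3],
      resno = resno, aa = aa, chain = "A")
  rows[[length(rows) + 1L]] <- data.frame(
    name = "CA", x = ca[1], y = ca[2], z = ca[3],
    resno = resno, aa = aa, chain = "A")
  do.call(rbind, rows)
}

toy_structure <- function(blocks, domains = NULL) {
  structure_model(do.call(rbind, blocks), domains = domains)
}

# A conservation profile matching a structure's numbering, with given
# grades (default: everything grade 9).
profile_for <- function(s, grades = NULL) {
  pos <- as.integer(names(s$sequence))
  if (is.null(grades)) grades <- rep(9L, length(pos))
  out <- data.frame(position = pos, aa = unname(s$sequence),
                    score = grades / 9, grade = as.integer(grades),
                    gap_fraction = 0, low_confidence = FALSE,
                    column = pos, stringsAsFactors = FALSE)
  attr(out, "ref_id") <- "REF"
  attr(out, "mode") <- "identity"
  class(out) <- c("conservation_profile", "data.frame")
  out
}

# Random single-atom-per-residue structure for component oracle tests.
random_structure <- function(n, span = 30, seed = 1) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n, 0, span), ncol = 3)
  blocks <- lapply(seq_len(n), function(i)
    res_block(i, if (i %% 2 == 0) "H" else "C", fun = xyz[i, ]))
  toy_structure(blocks)
}

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
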