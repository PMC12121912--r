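## exhaustive-pathway NG86 oracle, written against Biostrings' genetic code
## (independent of the implementation's codon table)
oracle_ng86 <- function(x, y) {
  code <- Biostrings::GENETIC_CODE
  tr <- function(cd) unname(code[cd])
  nc <- nchar(x) / 3
  cx <- substring(x, 3 * (1:nc) - 2, 3 * (1:nc))
  cy <- substring(y, 3 * (1:nc) - 2, 3 * (1:nc))
  site_count <- function(cd) {
    s <- 0
    for (i in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(cd, i, i))) {
      m <- cd; substr(m, i, i) <- b
      if (tr(m) == tr(cd)) s <- s + 1 / 3
    }
    s
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  diff_count <- function(a, b) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    acc <- list()
    for (ord in perms(pos)) {
      cur <- a; s <- 0; n <- 0; stopped <- FALSE
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(b, p, p)
        if (tr(nxt) == "*" || tr(cur) == "*") stopped <- TRUE
        if (tr(nxt) == tr(cur)) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      acc[[length(acc) + 1]] <- c(s, n, stopped)
    }
    m <- do.call(rbind, acc)
    ok <- m[, 3] == 0
    if (!any(ok)) ok <- rep(TRUE, nrow(m))
    c(mean(m[ok, 1]), mean(m[ok, 2]))
  }
  S <- mean(c(sum(sapply(cx, site_count)), sum(sapply(cy, site_count))))
  d <- rowSums(mapply(diff_count, cx, cy))
  list(N = 3 * nc - S, S = S, Sd = d[1], Nd = d[2])
}
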