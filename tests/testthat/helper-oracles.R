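# Independent, deliberately naive transcriptions of the defining equations of
# every encoder and metric.  These are written as direct loops over the
# published formulas and share no code with the package implementation; the
# tests assert element-wise agreement.

ALPHA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
ALPHA21 <- c(ALPHA20, "O")

rand_fragment <- function(L = 35L, p_dummy = 0.05) {
  ch <- sample(ALPHA20, L, replace = TRUE)
  dummy <- runif(L) < p_dummy
  ch[dummy] <- "O"
  ch[(L + 1) %/% 2] <- "K"
  paste0(ch, collapse = "")
}

o_chars <- function(f) strsplit(f, "")[[1]]

oracle_aac <- function(f) {
  ch <- o_chars(f)
  ch <- ch[ch != "O"]
  out <- numeric(20)
  if (length(ch) == 0) return(out)
  for (i in 1:20) out[i] <- sum(ch == ALPHA20[i]) / length(ch)
  out
}

oracle_dpc <- function(f) {
  ch <- o_chars(f); L <- length(ch)
  out <- numeric(400)
  k <- 0
  for (a in ALPHA20) for (b in ALPHA20) {
    k <- k + 1
    cnt <- 0
    for (i in 1:(L - 1)) if (ch[i] == a && ch[i + 1] == b) cnt <- cnt + 1
    out[k] <- cnt / (L - 1)
  }
  out
}

oracle_dde <- function(f) {
  codons <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3, K = 2,
              L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6, T = 4, V = 4,
              W = 1, Y = 2)
  ch <- o_chars(f); L <- length(ch)
  dc <- oracle_dpc(f)
  out <- numeric(400)
  k <- 0
  for (a in ALPHA20) for (b in ALPHA20) {
    k <- k + 1
    tm <- (codons[[a]] / 61) * (codons[[b]] / 61)
    tv <- tm * (1 - tm) / (L - 1)
    out[k] <- (dc[k] - tm) / sqrt(tv)
  }
  out
}

oracle_eaac <- function(f, w = 5L) {
  ch <- o_chars(f); L <- length(ch)
  out <- numeric(0)
  for (s in 1:(L - w + 1)) {
    win <- ch[s:(s + w - 1)]
    for (a in ALPHA20) out <- c(out, sum(win == a) / w)
  }
  out
}

oracle_egaac <- function(f, w = 5L) {
  gr <- list(strsplit("GAVLMI", "")[[1]], strsplit("FYW", "")[[1]],
             strsplit("KRH", "")[[1]], strsplit("DE", "")[[1]],
             strsplit("STCPNQ", "")[[1]])
  ch <- o_chars(f); L <- length(ch)
  out <- numeric(0)
  for (s in 1:(L - w + 1)) {
    win <- ch[s:(s + w - 1)]
    for (g in gr) out <- c(out, sum(win %in% g) / w)
  }
  out
}

oracle_bina <- function(f) {
  ch <- o_chars(f)
  out <- numeric(0)
  for (c0 in ch) out <- c(out, as.numeric(ALPHA21 == c0))
  out
}

oracle_num <- function(f) {
  ch <- o_chars(f)
  ctr <- (length(ch) + 1) %/% 2
  vapply(ch[-ctr], function(c0) which(ALPHA21 == c0), numeric(1))
}

oracle_blosum62 <- function(f) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62
  ch <- o_chars(f)
  out <- numeric(0)
  for (c0 in ch)
    out <- c(out, if (c0 == "O") numeric(20) else as.numeric(b[c0, ALPHA20]))
  out
}

oracle_cksaap <- function(f, gaps = 0:4) {
  ch <- o_chars(f); L <- length(ch)
  out <- numeric(0)
  for (k in gaps) {
    n_tot <- L - k - 1
    for (a in ALPHA21) for (b in ALPHA21) {
      cnt <- 0
      for (i in 1:n_tot) if (ch[i] == a && ch[i + k + 1] == b) cnt <- cnt + 1
      out <- c(out, cnt / n_tot)
    }
  }
  out
}

oracle_ebgw <- function(f, J = 5L) {
  c1 <- strsplit("AFGILMPVW", "")[[1]]; c2 <- strsplit("CNQSTY", "")[[1]]
  c3 <- c("D", "E"); c4 <- c("H", "K", "R")
  ch <- o_chars(f); L <- length(ch)
  hs <- list(as.numeric(ch %in% c(c1, c2)), as.numeric(ch %in% c(c1, c3)),
             as.numeric(ch %in% c(c1, c4)))
  out <- numeric(0)
  for (h in hs) for (j in 1:J) {
    len <- floor(j * L / J)
    out <- c(out, sum(h[1:len]) / len)
  }
  out
}

oracle_pwaa <- function(f) {
  ch <- o_chars(f); L <- length(ch)
  m <- (L - 1) %/% 2
  out <- numeric(21)
  for (i in 1:21) {
    acc <- 0
    for (j in (-m):m) {
      v <- as.numeric(ch[j + m + 1] == ALPHA21[i])
      acc <- acc + v * (j + abs(j) / m)
    }
    out[i] <- acc / (m * (m + 1))
  }
  out
}

oracle_profile <- function(f) {
  ch <- o_chars(f); L <- length(ch)
  vapply(ch, function(c0) sum(ch == c0) / L, numeric(1))
}

oracle_ebpr <- function(f) {
  grp <- function(c0) {
    if (c0 %in% strsplit("AFGILMPVW", "")[[1]]) "C1"
    else if (c0 %in% strsplit("CNQSTY", "")[[1]]) "C2"
    else if (c0 %in% c("D", "E")) "C3"
    else if (c0 %in% c("H", "K", "R")) "C4"
    else "X"
  }
  g <- vapply(o_chars(f), grp, character(1))
  L <- length(g)
  vapply(g, function(c0) sum(g == c0) / L, numeric(1))
}

oracle_bpb <- function(train, labels, query, alpha = 1) {
  L <- nchar(query)
  qc <- o_chars(query)
  pos <- train[labels == "positive"]; neg <- train[labels == "negative"]
  xp <- xn <- numeric(L)
  for (i in 1:L) {
    xp[i] <- (sum(vapply(pos, function(t) o_chars(t)[i] == qc[i],
                         logical(1))) + alpha) / (length(pos) + 21 * alpha)
    xn[i] <- (sum(vapply(neg, function(t) o_chars(t)[i] == qc[i],
                         logical(1))) + alpha) / (length(neg) + 21 * alpha)
  }
  c(xp, xn)
}

oracle_pwm <- function(positives, query, alpha = 1) {
  L <- nchar(query)
  qc <- o_chars(query)
  out <- numeric(L)
  for (i in 1:L)
    out[i] <- (sum(vapply(positives, function(t) o_chars(t)[i] == qc[i],
                          logical(1))) + alpha) /
      (length(positives) + 21 * alpha)
  out
}

oracle_knn <- function(train, labels, query,
                       k_fracs = c(0.01, 0.02, 0.05, 0.10)) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62[ALPHA20, ALPHA20]
  s <- (b - min(b)) / (max(b) - min(b))
  simfun <- function(a, c0) {
    if (a == "O" || c0 == "O") 0 else s[a, c0]
  }
  L <- nchar(query)
  qc <- o_chars(query)
  d <- vapply(train, function(t) {
    tc <- o_chars(t)
    1 - sum(mapply(simfun, qc, tc)) / L
  }, numeric(1))
  ord <- order(d)
  vapply(k_fracs, function(k) {
    kk <- max(1, ceiling(k * length(train)))
    mean(labels[ord[1:kk]] == "positive")
  }, numeric(1))
}

oracle_tfidf <- function(corpus, query) {
  out <- numeric(20)
  for (i in 1:20) {
    t0 <- ALPHA20[i]
    tf <- sum(o_chars(query) == t0) / nchar(query)
    df <- sum(vapply(corpus, function(d) t0 %in% o_chars(d), logical(1)))
    idf <- if (df == 0) 0 else log10(length(corpus) / df)
    out[i] <- tf * idf
  }
  out
}

oracle_tfcrf <- function(corpus, labels, query, eps = 1e-6) {
  out <- numeric(40)
  pos <- corpus[labels == "positive"]; neg <- corpus[labels == "negative"]
  for (i in 1:20) {
    t0 <- ALPHA20[i]
    has <- function(set) vapply(set, function(d) t0 %in% o_chars(d),
                                logical(1))
    rf_p <- sum(has(pos)) / length(pos)
    rf_n <- sum(has(neg)) / length(neg)
    ltf <- log(1 + sum(o_chars(query) == t0))
    out[i] <- ltf * rf_p / (rf_n + eps)
    out[20 + i] <- ltf * rf_n / (rf_p + eps)
  }
  out
}

oracle_sfpssm <- function(scores, residues, delta = 7) {
  f <- scores
  f[f < 0] <- 0
  f[f > delta] <- delta
  ch <- strsplit(residues, "")[[1]]
  out <- numeric(0)
  for (i in ALPHA20) {
    sums <- numeric(20)
    for (k in seq_along(ch))
      if (ch[k] == i) sums <- sums + f[k, ]
    out <- c(out, sums)
  }
  out
}

# ---- metrics oracles -------------------------------------------------------

oracle_metrics <- function(TP, TN, FP, FN) {
  list(accuracy = (TN + TP) / (TN + FP + TP + FN),
       sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       precision = TP / (TP + FP),
       f1 = {
         p <- TP / (TP + FP); r <- TP / (TP + FN)
         2 * p * r / (p + r)
       },
       mcc = (TN * TP - FN * FP) /
         sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)),
       kappa = 2 * (TP * TN - FN * FP) /
         ((TP + FP) * (FP + TN) + (TP + FN) * (FN + TN)))
}

# pairwise Mann-Whitney AUC with ties counted one half
oracle_auc_ranksum <- function(scores, labels) {
  y <- labels == "positive"
  sp <- scores[y]; sn <- scores[!y]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# balanced random fragment set for fitted-encoder tests
rand_corpus <- function(n, L = 15L) {
  frags <- vapply(seq_len(n), function(i) rand_fragment(L), character(1))
  labels <- rep(c("positive", "negative"), length.out = n)
  list(fragments = frags, labels = labels)
}
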