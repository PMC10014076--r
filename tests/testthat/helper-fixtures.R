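# Fixture builders shared across the suite. Everything is generated in code
# at test time; nothing binary is stored in the repository.

# Write a minimal valid FCS 3.0 file (list mode, float32 data) and return
# its path. `events` is a numeric matrix, rows = cells.
write_fcs_fixture <- function(events, channels = colnames(events),
                              path = tempfile(fileext = ".fcs"),
                              version = "FCS3.0",
                              declared_tot = nrow(events),
                              truncate_data = 0L,
                              extra_keywords = list()) {
  events <- as.matrix(events)
  n_par <- ncol(events)
  if (is.null(channels)) channels <- paste0("CH", seq_len(n_par))
  kw <- c(
    "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
    "$PAR" = as.character(n_par), "$TOT" = as.character(declared_tot),
    "$NEXTDATA" = "0"
  )
  for (i in seq_len(n_par)) {
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dN", i)] <- channels[i]
    kw[sprintf("$P%dR", i)] <- "262144"
    kw[sprintf("$P%dE", i)] <- "0,0"
  }
  for (nm in names(extra_keywords)) kw[nm] <- extra_keywords[[nm]]

  delim <- "/"
  text <- paste0(delim, paste0(names(kw), delim, unname(kw), delim,
                               collapse = ""))
  text_raw <- charToRaw(text)
  header_len <- 58L
  text_begin <- header_len
  text_end <- text_begin + length(text_raw) - 1L
  data_begin <- text_end + 1L
  n_vals <- length(events) - truncate_data
  data_end <- data_begin + 4L * n_vals - 1L
  pad <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0(version, "    ", pad(text_begin), pad(text_end),
                   pad(data_begin), pad(data_end), pad(0), pad(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeBin(text_raw, con)
  vals <- as.numeric(t(events))[seq_len(n_vals)]
  writeBin(vals, con, size = 4, endian = "little")
  path
}

# Dataset whose per-dose outputs are drawn from given normal populations.
make_normal_dataset <- function(means, sds = rep(1, length(means)),
                                n = 200L, doses = seq_along(means) - 1,
                                seed = 1L) {
  set.seed(seed)
  outputs <- mapply(function(m, s) rnorm(n, m, s), means, sds,
                    SIMPLIFY = FALSE)
  dose_response_dataset(doses, outputs)
}

# Binary symmetric channel conditional.
bsc <- function(eps) matrix(c(1 - eps, eps, eps, 1 - eps), 2, 2, byrow = TRUE)

# Binary entropy in bits.
h2 <- function(e) {
  ifelse(e <= 0 | e >= 1, 0, -e * log2(e) - (1 - e) * log2(1 - e))
}

# Exhaustive capacity search over the input simplex on a coarse grid,
# independent of the Blahut-Arimoto path (direct MI evaluation).
grid_search_capacity <- function(Q, step = 0.01) {
  m <- nrow(Q)
  mi <- function(p) {
    q <- as.vector(p %*% Q)
    tot <- 0
    for (i in seq_len(m)) {
      if (p[i] <= 0) next
      nz <- Q[i, ] > 0
      tot <- tot + p[i] * sum(Q[i, nz] * (log2(Q[i, nz]) - log2(q[nz])))
    }
    tot
  }
  stopifnot(m %in% c(2L, 3L))
  best <- 0
  grid <- seq(0, 1, by = step)
  if (m == 2L) {
    for (p1 in grid) best <- max(best, mi(c(p1, 1 - p1)))
  } else {
    for (p1 in grid) for (p2 in seq(0, 1 - p1, by = step)) {
      best <- max(best, mi(c(p1, p2, 1 - p1 - p2)))
    }
  }
  best
}

# Random row-stochastic matrix.
random_stochastic <- function(m, k) {
  Q <- matrix(rexp(m * k), m, k)
  Q / rowSums(Q)
}
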