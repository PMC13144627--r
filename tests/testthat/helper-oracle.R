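# Independent brute-force scar-metric implementations that apply the
# definitions literally, segment by segment, using only base loops. Kept
# deliberately separate from the package code paths: segments are handled
# as plain row lists, smoothing is re-implemented from the written rule,
# and no vectorized shortcuts are shared with gitax.

oracle_rows <- function(profile) {
  seg <- profile$segments
  lapply(seq_len(nrow(seg)), function(i) as.list(seg[i, ]))
}

oracle_hrd_loh <- function(profile, build, min_len = 15e6, tol = 1000) {
  count <- 0
  for (r in oracle_rows(profile)) {
    ci <- which(build$chrom == r$chrom)
    is_loh <- r$minor == 0 && r$major >= 1
    long_enough <- (r$end - r$start + 1) > min_len
    whole <- r$start <= 1 + tol && r$end >= build$length[ci] - tol
    if (is_loh && long_enough && !whole) count <- count + 1
  }
  count
}

oracle_ntai <- function(profile, build, tol = 1000) {
  count <- 0
  for (r in oracle_rows(profile)) {
    ci <- which(build$chrom == r$chrom)
    imbalanced <- r$major != r$minor
    at_telomere <- r$start <= 1 + tol || r$end >= build$length[ci] - tol
    crosses_cen <- r$start < build$cen_start[ci] && r$end > build$cen_end[ci]
    if (imbalanced && at_telomere && !crosses_cen) count <- count + 1
  }
  count
}

# Literal smoothing: repeatedly merge equal adjacent states, then delete the
# shortest sub-threshold segment, closing the gap at its midpoint.
oracle_smooth <- function(rows, min_len = 3e6) {
  repeat {
    # merge pass
    i <- 2
    while (i <= length(rows)) {
      a <- rows[[i - 1]]; b <- rows[[i]]
      if (a$chrom == b$chrom && a$major == b$major && a$minor == b$minor) {
        rows[[i - 1]]$end <- b$end
        rows[[i]] <- NULL
      } else i <- i + 1
    }
    lens <- vapply(rows, function(r) r$end - r$start + 1, numeric(1))
    small <- which(lens < min_len)
    if (length(small) == 0) return(rows)
    k <- small[order(lens[small])][1]
    r <- rows[[k]]
    left <- if (k > 1 && rows[[k - 1]]$chrom == r$chrom) k - 1 else NA
    right <- if (k < length(rows) && rows[[k + 1]]$chrom == r$chrom) k + 1 else NA
    if (!is.na(left) && !is.na(right)) {
      mid <- floor((r$start + r$end) / 2)
      rows[[left]]$end <- mid
      rows[[right]]$start <- mid + 1
    } else if (!is.na(left)) {
      rows[[left]]$end <- r$end
    } else if (!is.na(right)) {
      rows[[right]]$start <- r$start
    }
    rows[[k]] <- NULL
  }
}

oracle_lst <- function(profile, build, min_seg = 10e6, smooth_len = 3e6) {
  rows <- oracle_smooth(oracle_rows(profile), smooth_len)
  # clip every segment to each arm; [1, cen_start] and [cen_end, length]
  arm_rows <- list()
  for (r in rows) {
    ci <- which(build$chrom == r$chrom)
    p <- list(chrom = r$chrom, arm = "p", start = r$start,
              end = min(r$end, build$cen_start[ci]),
              major = r$major, minor = r$minor)
    q <- list(chrom = r$chrom, arm = "q",
              start = max(r$start, build$cen_end[ci]), end = r$end,
              major = r$major, minor = r$minor)
    if (p$start <= p$end) arm_rows[[length(arm_rows) + 1]] <- p
    if (q$start <= q$end) arm_rows[[length(arm_rows) + 1]] <- q
  }
  count <- 0
  for (ci in seq_len(nrow(build))) {
    for (arm in c("p", "q")) {
      a <- Filter(function(r) r$chrom == build$chrom[ci] && r$arm == arm,
                  arm_rows)
      if (length(a) < 2) next
      a <- a[order(vapply(a, `[[`, numeric(1), "start"))]
      for (k in 2:length(a)) {
        prev <- a[[k - 1]]; cur <- a[[k]]
        big <- (prev$end - prev$start + 1) >= min_seg &&
          (cur$end - cur$start + 1) >= min_seg
        differs <- prev$major != cur$major || prev$minor != cur$minor
        adjacent <- (cur$start - prev$end - 1) <= smooth_len
        if (big && differs && adjacent) count <- count + 1
      }
    }
  }
  count
}
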