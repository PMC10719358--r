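#' Hotspot-detection parameters
#'
#' @param bw Gaussian kernel bandwidth in bp.
#' @param num_trial Permutation trials for the null distribution.
#' @param alpha Family-wise significance level.
#' @param grid_step Density evaluation grid step in bp.
#' @param mode `"maxnull"` (default): threshold at the `(1 - alpha)`
#'   quantile of each trial's maximum density (family-wise control);
#'   `"pointwise"`: per-grid-point quantile.
#' @return List of class `hotspot_params`.
#' @export
hotspot_params <- function(bw = 200000, num_trial = 1000L, alpha = 0.05,
                           grid_step = 10000L,
                           mode = c("maxnull", "pointwise")) {
  stopifnot(bw > 0, num_trial >= 1, alpha > 0, alpha < 1, grid_step > 0)
  structure(list(bw = bw, num_trial = as.integer(num_trial), alpha = alpha,
                 grid_step = as.integer(grid_step), mode = match.arg(mode)),
            class = "hotspot_params")
}

sv_midpoint <- function(svs) {
  ifelse(svs$svtype == "INS", svs$start,
         as.integer(floor((svs$start + svs$end) / 2)))
}

#' Binned genome-wide SV density
#'
#' Counts SVs per fixed-size bin (assignment by midpoint; insertion point
#' for INS), one column per SV type, with optional per-track interval
#' counts (track elements assigned by their midpoints).
#'
#' @param svs SV tibble.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (default 500 kb); the last partial bin
#'   is kept.
#' @param tracks Optional named list of interval tibbles
#'   ([read_intervals()]).
#' @return Tibble with `chrom`, `bin_start`, `bin_end`, one count column
#'   per SV type present plus `total`, and one column per track.
#' @export
binned_density <- function(svs, chrom_sizes, bin_size = 500000L,
                           tracks = NULL) {
  svs <- as_tibble(svs)
  unknown <- setdiff(unique(svs$chrom), names(chrom_sizes))
  if (base::length(unknown) > 0) {
    abort(paste0("SV on chromosome(s) absent from chrom_sizes: ",
                 paste(unknown, collapse = ", ")))
  }
  grid <- purrr::map_dfr(names(chrom_sizes), function(ch) {
    n_bins <- ceiling(chrom_sizes[[ch]] / bin_size)
    tibble(chrom = ch,
           bin_start = as.integer((seq_len(n_bins) - 1) * bin_size),
           bin_end = as.integer(pmin(seq_len(n_bins) * bin_size,
                                     chrom_sizes[[ch]])))
  })
  bin_of <- function(chrom, pos) {
    paste0(chrom, ":", floor(pos / bin_size))
  }
  grid_key <- bin_of(grid$chrom, grid$bin_start)
  count_into <- function(chrom, pos) {
    tab <- table(factor(bin_of(chrom, pos), levels = grid_key))
    as.integer(tab)
  }
  if (nrow(svs) > 0) {
    mid <- sv_midpoint(svs)
    for (tp in intersect(SV_TYPES, unique(svs$svtype))) {
      sel <- svs$svtype == tp
      grid[[tp]] <- count_into(svs$chrom[sel], mid[sel])
    }
    grid$total <- count_into(svs$chrom, mid)
  } else {
    grid$total <- 0L
  }
  for (nm in names(tracks %||% list())) {
    tr <- tracks[[nm]]
    keep <- tr$chrom %in% names(chrom_sizes)
    grid[[nm]] <- count_into(tr$chrom[keep],
                             floor((tr$start[keep] + tr$end[keep]) / 2))
  }
  grid
}

#' Pairwise Pearson correlation of binned densities
#'
#' @param table Output of [binned_density()] (or any tibble whose numeric
#'   columns are per-bin counts); at least 3 bins and 2 numeric columns.
#' @return Symmetric correlation matrix with unit diagonal; columns with
#'   zero variance are flagged `NA` and listed in attribute `constant`.
#' @export
density_correlation <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("bin_start", "bin_end"))]
  if (ncol(num) < 2) abort("need at least two count columns")
  if (nrow(num) < 3) abort("need at least three bins")
  constant <- names(num)[vapply(num, function(x) sd(x) == 0, logical(1))]
  m <- suppressWarnings(cor(as.matrix(num)))
  diag(m) <- 1
  attr(m, "constant") <- constant
  m
}

#' Kernel-density SV hotspots with a permutation null
#'
#' Per chromosome, a Gaussian kernel density of SV midpoints (bandwidth
#' `bw`) is evaluated on a `grid_step` grid and scaled to events per bp
#' (density times the number of events).  The null re-places the same
#' number of midpoints uniformly on the chromosome `num_trial` times; the
#' detection threshold is the `(1 - alpha)` quantile of the null per-trial
#' maximum density (or the pointwise quantile in `"pointwise"` mode).
#' Hotspots are maximal grid runs above threshold.
#'
#' @param svs SV tibble.
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param params [hotspot_params()].
#' @param seed Integer seed (results deterministic given it).
#' @return Tibble `chrom`, `start`, `end`, `peak_density` (events/bp),
#'   `empirical_p` = `(1 + #trials with max >= peak) / (num_trial + 1)`.
#' @export
kde_hotspots <- function(svs, chrom_sizes, params = hotspot_params(),
                         seed = 1L) {
  svs <- as_tibble(svs)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  peak_density = numeric(), empirical_p = numeric())
  if (nrow(svs) == 0) return(empty)
  set.seed(seed)
  svs <- svs[sv_order(svs), ]  # call order-invariance
  out <- list()
  for (ch in names(chrom_sizes)) {
    mids <- sv_midpoint(svs[svs$chrom == ch, ])
    n <- base::length(mids)
    if (n == 0) {
      inform(paste0("kde_hotspots: no SVs on ", ch, ", skipped"))
      next
    }
    L <- chrom_sizes[[ch]]
    n_grid <- max(16L, as.integer(ceiling(L / params$grid_step)) + 1L)
    dens <- function(x) {
      density(x, bw = params$bw, from = 0, to = L, n = n_grid)$y *
        base::length(x)
    }
    obs <- dens(mids)
    null_max <- numeric(params$num_trial)
    null_mat <- if (params$mode == "pointwise") {
      matrix(0, params$num_trial, n_grid)
    }
    for (t in seq_len(params$num_trial)) {
      y <- dens(runif(n, 0, L))
      null_max[t] <- max(y)
      if (params$mode == "pointwise") null_mat[t, ] <- y
    }
    thr <- if (params$mode == "maxnull") {
      quantile(null_max, 1 - params$alpha, names = FALSE)
    } else {
      apply(null_mat, 2, quantile, probs = 1 - params$alpha)
    }
    above <- obs > thr
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    gx <- seq(0, L, length.out = n_grid)
    step <- gx[2] - gx[1]
    for (k in which(runs$values)) {
      i1 <- starts[k]; i2 <- ends[k]
      peak <- max(obs[i1:i2])
      out[[base::length(out) + 1]] <- tibble(
        chrom = ch,
        start = as.integer(max(0, floor(gx[i1] - step / 2))),
        end = as.integer(min(L, ceiling(gx[i2] + step / 2))),
        peak_density = peak,
        empirical_p = (1 + sum(null_max >= peak)) / (params$num_trial + 1)
      )
    }
  }
  if (base::length(out) == 0) return(empty)
  bind_rows(out)
}

#' Repeat/annotation-track enrichment of SVs
#'
#' Observed = fraction of SVs whose span (midpoint for INS) overlaps the
#' track; expected = mean of the same fraction over `n_perm` random
#' re-placements preserving each SV's chromosome and length.  The
#' genome-fraction shortcut (track bp / genome bp) is reported alongside.
#'
#' @param svs SV tibble.
#' @param track Interval tibble ([read_intervals()]); nonempty.
#' @param chrom_sizes Named chromosome lengths.
#' @param n_perm Permutations (>= 1).
#' @param seed Integer seed.
#' @return List: `observed`, `expected`, `fold`, `p` (two-sided
#'   permutation p), `genome_fraction` (track coverage shortcut).
#' @export
repeat_enrichment <- function(svs, track, chrom_sizes, n_perm = 200L,
                              seed = 1L) {
  svs <- as_tibble(svs)
  track <- as_tibble(track)
  if (nrow(track) == 0) abort("empty annotation track")
  stopifnot(n_perm >= 1)
  set.seed(seed)
  tr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start + 1L, track$end)))
  frac_overlap <- function(chrom, start, end) {
    q <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(start + 1L, pmax(end, start + 1L)))
    mean(IRanges::overlapsAny(q, tr))
  }
  s0 <- svs$start
  e0 <- ifelse(svs$svtype == "INS", svs$start + 1L, svs$end)
  observed <- frac_overlap(svs$chrom, s0, e0)
  lens <- e0 - s0
  maxpos <- chrom_sizes[svs$chrom] - lens
  if (any(maxpos < 0)) abort("SV longer than its chromosome")
  perm <- vapply(seq_len(n_perm), function(i) {
    ns <- as.integer(floor(runif(nrow(svs), 0, maxpos + 1)))
    frac_overlap(svs$chrom, ns, ns + lens)
  }, numeric(1))
  expected <- mean(perm)
  if (expected == 0) abort("expected overlap is zero; fold undefined")
  p <- (1 + sum(abs(perm - expected) >= abs(observed - expected))) /
    (n_perm + 1)
  cov_bp <- sum(GenomicRanges::width(tr))
  list(observed = observed, expected = expected,
       fold = observed / expected, p = p,
       genome_fraction = cov_bp / sum(unlist(chrom_sizes)))
}
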