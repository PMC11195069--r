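## Sequential (hierarchical) bounds on coupling strengths.
##
## The condition tables order the couplings so that each parameter's
## admissible interval depends only on parameters earlier in the hierarchy.
## Abeta->I weights have closed-form box bounds; the remaining stages are
## either closed-form interval intersections (evaluated on a rate grid plus
## Lambert-W candidates) or conditional-feasibility intervals: because all
## constraints are affine in the downstream couplings once the Abeta->I
## weights are fixed, the set of values for which the downstream intervals
## are non-empty is itself an interval, located by a vectorised scan whose
## edges are refined by nested re-scanning.

rowMax <- function(M) M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
rowMin <- function(M) -rowMax(-M)

iv_or_null <- function(lo, hi) if (lo > hi) NULL else c(lo, hi)

## interval of x in [a, b] where feas_vec(xs) (vectorised, logical) is TRUE;
## the feasible set is assumed to be an interval (possibly empty)
interval_from_scan <- function(feas_vec, a, b, n_scan = 33L, rounds = 3L,
                               n_ref = 9L) {
  if (a > b) return(NULL)
  xs <- seq(a, b, length.out = n_scan)
  ok <- feas_vec(xs)
  if (!any(ok)) return(NULL)
  i1 <- which(ok)[1L]; i2 <- which(ok)[sum(ok)]
  lo <- xs[i1]; hi <- xs[i2]
  if (i1 > 1L) {
    l <- xs[i1 - 1L]; h <- lo
    for (r in seq_len(rounds)) {
      zs <- seq(l, h, length.out = n_ref)
      okz <- feas_vec(zs)
      j <- which(okz)[1L]
      h <- zs[j]; if (j > 1L) l <- zs[j - 1L]
    }
    lo <- h
  }
  if (i2 < n_scan) {
    l <- hi; h <- xs[i2 + 1L]
    for (r in seq_len(rounds)) {
      zs <- seq(l, h, length.out = n_ref)
      okz <- feas_vec(zs)
      j <- which(okz)[sum(okz)]
      l <- zs[j]; if (j < n_ref) h <- zs[j + 1L]
    }
    hi <- l
  }
  c(lo, hi)
}

## scalar-feasibility variant built on the same machinery
cond_interval <- function(feas, a, b, n_scan = 33L, rounds = 3L) {
  interval_from_scan(function(xs) vapply(xs, feas, logical(1)),
                     a, b, n_scan = n_scan, rounds = rounds)
}

## per-circuit stage machinery; returns a list of functions, one per stage
## in sampling order, each mapping the partial coupling vector (named) to
## an interval c(lo, hi) or NULL
stage_functions <- function(circuit, n_grid = 201) {
  k <- aps_consts()
  ip <- k$ip; ep <- k$ep
  fr <- circuit$input_rate_range
  f_lo <- fr[1]; f_hi <- fr[2]
  box_I <- c(k$i_thr / f_lo, k$i_max / f_hi)    # Abeta->I weights
  .cache <- new.env(parent = emptyenv())        # memoise within one draw
  ## one common rate grid for every stage, so multi-population rows combine
  ## consistently and bounds agree with the grid used by aps_feasible();
  ## existence scans run on a subgrid (a relaxation, so rejections stay
  ## sound; the seed sampler re-verifies accepted draws on the full grid)
  fg_base <- seq(fr[1], fr[2], length.out = n_grid)
  ix_s <- unique(round(seq(1L, n_grid, length.out = min(51L, n_grid))))
  fI_of <- function(g_in) {
    key <- sprintf("%.15g", g_in)
    got <- .cache[[key]]
    if (!is.null(got)) return(got)
    .cache[[key]] <- res <- list(fg = fg_base,
                                 fI = inhibitory_rate(fg_base, g_in, ip))
    res
  }
  ## simple-circuit style interval for an I->E weight given the Abeta drive:
  ## intersection of the pain-inhibition/lower-bound rows with the
  ## ablation-row caps on the downstream Abeta->E weight
  gIE_interval <- function(r) {
    fg <- r$fg; fI <- r$fI
    mr <- min(fI / fg)                     # min_f fI/f
    L <- (k$e_thr / f_lo) / mr
    U <- min(((k$e_max / f_hi) * fg + k$e_min) / fI)
    phi <- function(g) g * mr - max((g * fI - k$e_min) / fg)
    U2 <- U
    if (phi(U) < 0) {
      l <- 0; h <- U
      for (q in 1:50) { m <- (l + h) / 2; if (phi(m) >= 0) l <- m else h <- m }
      U2 <- l
    }
    iv_or_null(L, min(U, U2))
  }
  gAbE_interval <- function(g_syn, r) {
    fg <- r$fg; fI <- r$fI
    lo <- max(k$e_thr / f_lo, max((g_syn * fI - k$e_min) / fg))
    hi <- min(k$e_max / f_hi, min(g_syn * fI / fg))
    iv_or_null(lo, hi)
  }
  res <- switch(circuit$name,
  simple = list(
    gAbI = function(partial) box_I,
    gIE = function(partial) gIE_interval(fI_of(partial[["gAbI"]])),
    gAbE = function(partial) gAbE_interval(partial[["gIE"]], fI_of(partial[["gAbI"]]))
  ),
  static = {
    ## exact interval for gI2E given (gE, gI1E)
    g22_iv <- function(gE, g11, r1, r2) {
      fg <- r1$fg
      lo <- max((gE * fg - k$e_max) / r2$fI, (gE * fg - g11 * r1$fI) / r2$fI, 0)
      hi <- min((gE * fg - k$e_thr) / r2$fI, (gE * fg - g11 * r1$fI + k$e_min) / r2$fI)
      iv_or_null(lo, hi)
    }
    ## vectorised feasibility over gI1E candidates: non-empty gI2E interval
    ## (column-recycled arithmetic: for an m x k matrix, rep(v, each = m)
    ## expands a length-k vector columnwise without sweep's transposes)
    g11_feasible <- function(g11s, gE, r1, r2, sub = ix_s) {
      fg <- r1$fg; f1 <- r1$fI; f2 <- r2$fI
      if (!is.null(sub)) { fg <- fg[sub]; f1 <- f1[sub]; f2 <- f2[sub] }
      lo_c <- max(max((gE * fg - k$e_max) / f2), 0)
      hi_c <- min((gE * fg - k$e_thr) / f2)
      if (lo_c > hi_c) return(rep(FALSE, length(g11s)))
      m <- length(g11s)
      C <- rep(gE * fg / f2, each = m) - outer(g11s, f1 / f2)
      lo_v <- rowMax(C)
      hi_v <- rowMin(C + rep(k$e_min / f2, each = m))
      pmax(lo_c, lo_v, 0) <= pmin(hi_c, hi_v)
    }
    g11_range <- function(gE, r1) {
      fg <- r1$fg
      l11 <- max(max((gE * fg - k$e_max) / r1$fI), 0)
      h11 <- min((gE * fg - k$e_thr) / r1$fI)
      iv_or_null(l11, h11)
    }
    g11_iv <- function(gE, r1, r2) {
      rg <- g11_range(gE, r1)
      if (is.null(rg)) return(NULL)
      interval_from_scan(function(xs) g11_feasible(xs, gE, r1, r2), rg[1], rg[2])
    }
    ## vectorised existence check over gAbE candidates: for each gE, probe
    ## 25 gI1E values across its direct range and test whether any leaves a
    ## non-empty gI2E interval (one flattened (gE, gI1E, f) tensor pass)
    g11_exists_vec <- function(gEs, r1, r2, sub = ix_s) {
      fg <- r1$fg; f1 <- r1$fI; f2 <- r2$fI
      if (!is.null(sub)) { fg <- fg[sub]; f1 <- f1[sub]; f2 <- f2[sub] }
      n1 <- length(gEs)
      A1 <- outer(gEs, fg / f1)                     # n1 x k
      l11 <- pmax(rowMax(A1 - rep(k$e_max / f1, each = n1)), 0)
      h11 <- rowMin(A1 - rep(k$e_thr / f1, each = n1))
      A2 <- outer(gEs, fg / f2)
      lo_c <- pmax(rowMax(A2 - rep(k$e_max / f2, each = n1)), 0)
      hi_c <- rowMin(A2 - rep(k$e_thr / f2, each = n1))
      out <- l11 <= h11 & lo_c <= hi_c
      live <- which(out)
      if (!length(live)) return(out)
      np <- 15L
      nl <- length(live)
      m <- np * nl
      fr01 <- seq(0, 1, length.out = np)
      gE_rep <- rep(gEs[live], each = np)
      g11_rep <- rep(l11[live], each = np) +
        rep(fr01, times = nl) * rep(h11[live] - l11[live], each = np)
      C <- outer(gE_rep, fg / f2) - outer(g11_rep, f1 / f2)
      lo_v <- rowMax(C)
      hi_v <- rowMin(C + rep(k$e_min / f2, each = m))
      ok_pair <- pmax(rep(lo_c[live], each = np), lo_v, 0) <=
        pmin(rep(hi_c[live], each = np), hi_v)
      out[live] <- colSums(matrix(ok_pair, np)) > 0L
      out
    }
    globals <- function(r) c(k$e_thr / min(r$fI), (k$e_max + k$e_min) / max(r$fI))
    list(
      gAbI1 = function(partial) box_I,
      gAbI2 = function(partial) box_I,
      gAbE = function(partial) {
        r1 <- fI_of(partial[["gAbI1"]]); r2 <- fI_of(partial[["gAbI2"]])
        gl1 <- globals(r1); gl2 <- globals(r2)
        if (gl1[1] > gl1[2] || gl2[1] > gl2[2]) return(NULL)
        fg <- r1$fg
        lo <- max(max((k$e_thr + gl2[1] * r2$fI) / fg),
                  max((k$e_thr + gl1[1] * r1$fI) / fg))
        hi <- min(min((gl1[2] * r1$fI + gl2[2] * r2$fI) / fg),
                  min((k$e_max + gl2[2] * r2$fI) / fg),
                  min((k$e_max + gl1[2] * r1$fI) / fg))
        if (lo > hi) return(NULL)
        ## coarse pre-screen: feasibility on a rate subgrid is a relaxation,
        ## so an all-infeasible coarse scan proves the interval empty and
        ## the coarse-feasible candidates bracket the true interval
        sub_c <- unique(round(seq(1L, length(r1$fg), length.out = 17L)))
        xs <- seq(lo, hi, length.out = 25L)
        okc <- g11_exists_vec(xs, r1, r2, sub_c)
        if (!any(okc)) return(NULL)
        i1 <- which(okc)[1L]; i2 <- which(okc)[sum(okc)]
        interval_from_scan(function(z) g11_exists_vec(z, r1, r2),
                           xs[max(i1 - 1L, 1L)], xs[min(i2 + 1L, 25L)],
                           n_scan = 13L, rounds = 1L)
      },
      gI1E = function(partial) {
        g11_iv(partial[["gAbE"]], fI_of(partial[["gAbI1"]]),
               fI_of(partial[["gAbI2"]]))
      },
      gI2E = function(partial) {
        g22_iv(partial[["gAbE"]], partial[["gI1E"]],
               fI_of(partial[["gAbI1"]]), fI_of(partial[["gAbI2"]]))
      })
  },
  dynamic = {
    ## E1 rates given the upstream gate, on the rate grid of r1
    e1_rates <- function(g11, gE1, r1) {
      key <- sprintf("e1_%.15g_%.15g", g11, gE1)
      got <- .cache[[key]]
      if (!is.null(got)) return(got)
      .cache[[key]] <- res <-
        list(ctrl = activation_rate(ep$v_rest + gE1 * r1$fg - g11 * r1$fI, ep),
             abl = activation_rate(ep$v_rest + gE1 * r1$fg, ep))
      res
    }
    ## exact interval for gAbE2 given (gI2E2, gE1E2)
    gAbE2_iv <- function(g22, gEE, r2, e1) {
      fg <- r2$fg
      lo <- max(0, max((g22 * r2$fI - k$e_min) / fg),
                max((k$e_thr + g22 * r2$fI - gEE * e1$abl) / fg),
                max((k$e_thr - gEE * e1$ctrl) / fg))
      hi <- min(min((g22 * r2$fI - gEE * e1$ctrl) / fg),
                min((k$e_max + g22 * r2$fI - gEE * e1$abl) / fg),
                min((k$e_max - gEE * e1$ctrl) / fg))
      iv_or_null(lo, hi)
    }
    ## vectorised feasibility over gI2E2 candidates: non-empty gAbE2 interval
    g22_feasible <- function(g22s, gEE, r2, e1) {
      fg <- r2$fg
      lo_c <- max(0, max((k$e_thr - gEE * e1$ctrl) / fg))
      hi_c <- min((k$e_max - gEE * e1$ctrl) / fg)
      P <- outer(g22s, r2$fI)                       # n x k
      lo_v <- pmax(rowMax(sweep(P - k$e_min, 2L, fg, "/")),
                   rowMax(sweep(sweep(P, 2L, k$e_thr - gEE * e1$abl, "+"),
                                2L, fg, "/")))
      hi_v <- pmin(rowMin(sweep(sweep(P, 2L, gEE * e1$ctrl, "-"), 2L, fg, "/")),
                   rowMin(sweep(sweep(P, 2L, k$e_max - gEE * e1$abl, "+"),
                                2L, fg, "/")))
      pmax(lo_c, lo_v) <= pmin(hi_c, hi_v)
    }
    g22_iv <- function(gEE, r2, e1) {
      rg <- g22_range_vec(gEE, r2, e1)
      if (!rg$ok) return(NULL)
      interval_from_scan(function(xs) g22_feasible(xs, gEE, r2, e1),
                         rg$lo, rg$hi)
    }
    ## vectorised existence over gE1E2 candidates: for each, probe 25 gI2E2
    ## values across its direct range in one flattened (gEE, g22, f) tensor
    ## pass; `sub` restricts to a rate subgrid (a relaxation, so an
    ## all-infeasible coarse scan is a sound rejection)
    ## per-gE1E2 analytic range for gI2E2, from the pairwise conditions of
    ## the E2 rows that decouple (the feasible gI2E2 window is a thin
    ## sliver of its naive upper bound, so probing without this tightening
    ## almost always misses it)
    g22_range_vec <- function(gEEs, r2, e1, sub = NULL) {
      fg <- r2$fg; f2 <- r2$fI; ec <- e1$ctrl; ea <- e1$abl
      if (!is.null(sub)) {
        fg <- fg[sub]; f2 <- f2[sub]; ec <- ec[sub]; ea <- ea[sub]
      }
      n1 <- length(gEEs)
      w <- 1 / fg
      Wn <- rep(w, each = n1)
      F2i <- rep(1 / f2, each = n1)
      Mec <- outer(gEEs, ec)
      Mea <- outer(gEEs, ea)
      lo3 <- rowMax((k$e_thr - Mec) * Wn)    # I2-abl fires floor on gAbE2
      hi3 <- rowMin((k$e_max - Mec) * Wn)    # I2-abl voltage ceiling
      ub <- rowMin(rep((k$e_max + k$e_min) * fg, each = n1) * F2i - Mec * F2i)
      L3 <- outer(lo3, fg)
      H3 <- outer(hi3, fg)
      g_lo <- pmax(0,
                   rowMax((L3 + Mec) * F2i),
                   rowMax((L3 - k$e_max + Mea) * F2i))
      g_hi <- pmin(ub,
                   rowMin((H3 - k$e_thr + Mea) * F2i),
                   rowMin((H3 + k$e_min) * F2i))
      ok <- hi3 >= lo3 & g_hi >= g_lo
      list(lo = g_lo, hi = g_hi, ok = ok)
    }
    g22_exists_vec <- function(gEEs, r2, e1, sub = ix_s) {
      rg <- g22_range_vec(gEEs, r2, e1, sub)
      out <- rg$ok
      live <- which(out)
      if (!length(live)) return(out)
      fg <- r2$fg; f2 <- r2$fI; ec <- e1$ctrl; ea <- e1$abl
      if (!is.null(sub)) {
        fg <- fg[sub]; f2 <- f2[sub]; ec <- ec[sub]; ea <- ea[sub]
      }
      w <- 1 / fg
      np <- 15L
      nl <- length(live)
      m <- np * nl
      fr01 <- seq(0, 1, length.out = np)
      gEE_rep <- rep(gEEs[live], each = np)
      g22_rep <- rep(rg$lo[live], each = np) +
        rep(fr01, times = nl) * rep(rg$hi[live] - rg$lo[live], each = np)
      P <- outer(g22_rep, f2 * w)                   # g22 * fI2 / f
      Qa <- outer(gEE_rep, ea * w)                  # gEE * fE1_abl / f
      Rc <- outer(gEE_rep, ec * w)                  # gEE * fE1_ctrl / f
      W1 <- rep(w, each = m)
      PQ <- P - Qa
      lo_v <- pmax(rowMax(P - k$e_min * W1),
                   rowMax(PQ + k$e_thr * W1),
                   rowMax(k$e_thr * W1 - Rc), 0)
      hi_v <- pmin(rowMin(P - Rc),
                   rowMin(PQ + k$e_max * W1),
                   rowMin(k$e_max * W1 - Rc))
      out[live] <- colSums(matrix(lo_v <= hi_v, np)) > 0L
      out
    }
    list(
      gAbI1 = function(partial) box_I,
      gAbI2 = function(partial) box_I,
      gI1E1 = function(partial) gIE_interval(fI_of(partial[["gAbI1"]])),
      gAbE1 = function(partial) gAbE_interval(partial[["gI1E1"]],
                                              fI_of(partial[["gAbI1"]])),
      gE1E2 = function(partial) {
        r1 <- fI_of(partial[["gAbI1"]]); r2 <- fI_of(partial[["gAbI2"]])
        e1 <- e1_rates(partial[["gI1E1"]], partial[["gAbE1"]], r1)
        ub <- min((k$e_max + k$e_min) * r1$fg / pmax(e1$abl, 1e-12))
        sub_c <- unique(round(seq(1L, length(r2$fg), length.out = 17L)))
        xs <- seq(0, ub, length.out = 21L)
        okc <- g22_exists_vec(xs, r2, e1, sub_c)
        if (!any(okc)) return(NULL)
        ## the coarse-feasible candidates bracket the true interval (the
        ## subgrid test is a relaxation), so refine only inside the bracket
        i1 <- which(okc)[1L]; i2 <- which(okc)[sum(okc)]
        interval_from_scan(function(z) g22_exists_vec(z, r2, e1),
                           xs[max(i1 - 1L, 1L)], xs[min(i2 + 1L, 21L)],
                           n_scan = 13L, rounds = 1L)
      },
      gI2E2 = function(partial) {
        r1 <- fI_of(partial[["gAbI1"]]); r2 <- fI_of(partial[["gAbI2"]])
        e1 <- e1_rates(partial[["gI1E1"]], partial[["gAbE1"]], r1)
        g22_iv(partial[["gE1E2"]], r2, e1)
      },
      gAbE2 = function(partial) {
        r1 <- fI_of(partial[["gAbI1"]]); r2 <- fI_of(partial[["gAbI2"]])
        e1 <- e1_rates(partial[["gI1E1"]], partial[["gAbE1"]], r1)
        gAbE2_iv(partial[["gI2E2"]], partial[["gE1E2"]], r2, e1)
      })
  })
  attr(res, "cache_env") <- .cache
  res
}

## drop memoised rate tables (called by the seed sampler between draws so
## the cache stays O(1))
reset_stage_cache <- function(stages) {
  env <- attr(stages, "cache_env")
  rm(list = ls(env), envir = env)
  invisible(NULL)
}

#' Admissible interval for the next coupling in the hierarchy
#'
#' Given values for every coupling below the queried one in the circuit's
#' sampling hierarchy, returns the interval the next coupling may take so
#' that the APS inequality system remains satisfiable.  Abeta->I weights
#' have closed-form box bounds; excitatory-side weights combine closed-form
#' rows (evaluated on a rate grid plus Lambert-W stationary points) with
#' conditional-feasibility intervals found by scanning downstream interval
#' non-emptiness and refining the edges.
#'
#' @param circuit A [circuit_spec()] object.
#' @param partial Named numeric vector containing exactly the couplings
#'   before the queried one in `circuit$sampling_order` (empty vector for
#'   the first).
#' @param n_grid Rate-grid resolution used in the interval evaluations.
#' @return Numeric length-2 interval `c(lo, hi)` (mV/Hz), or `NULL` when
#'   the interval is empty (the caller restarts).
#' @examples
#' cs <- circuit_spec("simple")
#' coupling_bounds(cs, numeric(0))          # gAbI in [2.07, 7.08]
#' @export
coupling_bounds <- function(circuit, partial = numeric(0), n_grid = 201) {
  stopifnot(inherits(circuit, "circuit_spec"))
  ord <- circuit$sampling_order
  np <- length(partial)
  if (np >= length(ord)) stop("all couplings already specified")
  if (np > 0 && !setequal(names(partial), ord[seq_len(np)]))
    stop("`partial` must contain exactly: ",
         paste(ord[seq_len(np)], collapse = ", "))
  stages <- stage_functions(circuit, n_grid)
  stages[[ord[np + 1L]]](partial)
}
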