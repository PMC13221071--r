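#' Run the full analysis pipeline on one session
#'
#' Orchestrates the analysis stages with a shared SWR exclusion mask and a
#' shared epoch segmentation: behavior (per-trial path lengths, visits,
#' breakpoint fit), spatial maps and goal classification per unit, LFP
#' block summaries (band power, PLV, n:m PLV, modulation index), theta
#' phase locking, pairwise short-latency coordination, assembly detection
#' and population decoding. Deterministic given `seed`; per-stage seeds
#' fan out from the master seed.
#'
#' @param session A `gs_session`.
#' @param seed Master seed.
#' @param n_surr Surrogates per pair/block for the coordination stage.
#' @param max_pairs Cap on ordered pairs in the coordination stage.
#' @param decode Run the decoding stage (the slowest stage).
#' @return A `gs_session_summary` list with one entry per stage and a
#'   `status` data frame recording per-stage success.
#' @export
run_pipeline <- function(session, seed = 1, n_surr = 200, max_pairs = 40,
                         decode = TRUE) {
  out <- list(session_id = session$session_id, seed = seed)
  status <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      warning(sprintf("stage %s failed: %s", name, conditionMessage(e)))
      NULL
    })
    status[[name]] <<- !is.null(res)
    res
  }

  track <- session$track
  sp_fun <- speed_interpolator(track)

  out$swr <- stage("swr", detect_swr(session$lfp$dCA1, sp_fun))
  swr_mask_fun <- if (!is.null(out$swr)) {
    mask <- out$swr$mask
    function(times) {
      idx <- pmin(pmax(round(times * LFP_FS) + 1, 1), length(mask))
      mask[idx]
    }
  } else NULL

  out$epochs <- stage("epochs", segment_epochs(track, session$goals_current,
                                               session$trials,
                                               session$start_box))
  out$behavior <- stage("behavior", {
    lens <- vapply(seq_len(nrow(session$trials)), function(i)
      trajectory_length(track, session$trials[i, ]), numeric(1))
    visits <- if (!is.null(session$probes))
      lapply(session$probes, function(w)
        detect_goal_visits(window_track(track, w[1], w[2]),
                           session$goals_current))
    else NULL
    list(path_lengths = lens, breakpoint = fit_breakpoint(lens),
         visits = visits)
  })

  out$spatial <- stage("spatial", {
    if (is.null(session$probes)) NULL else {
      labs <- lapply(session$units, function(u) {
        pre <- try(compute_rate_map(u, track, window = session$probes$pre),
                   silent = TRUE)
        post <- try(compute_rate_map(u, track, window = session$probes$post),
                    silent = TRUE)
        if (inherits(pre, "try-error") || inherits(post, "try-error"))
          return(NULL)
        list(pre_map = pre, post_map = post,
             info_pre = spatial_information(pre),
             class = classify_goal_cells(pre, post, session$goals_previous,
                                         session$goals_current))
      })
      names(labs) <- vapply(session$units, `[[`, "", "unit_id")
      labs
    }
  })

  out$oscillations <- stage("oscillations", {
    ep <- out$epochs
    n_lfp <- length(session$lfp$dCA1$samples)
    # filter once over the session; select epoch samples per block
    th1 <- phase_series(session$lfp$dCA1$samples, "theta")
    th2 <- phase_series(session$lfp$mOFC$samples, "theta")
    lg2 <- phase_series(session$lfp$mOFC$samples, "low_gamma")
    per_block <- lapply(1:4, function(b) {
      bw <- ep[ep$block == b, ]
      if (nrow(bw) == 0) return(NULL)
      # coupling metrics on concatenated epoch samples
      idx <- unlist(lapply(seq_len(nrow(bw)), function(i)
        max(1, round(bw$start_s[i] * LFP_FS)):min(n_lfp,
          round(bw$end_s[i] * LFP_FS))))
      # block power: per-trial Welch averaged over the block's trials
      tri <- session$trials[unique(bw$trial), , drop = FALSE]
      tp <- vapply(seq_len(nrow(tri)), function(i) {
        i0 <- max(1, round(tri$start_s[i] * LFP_FS))
        i1 <- min(n_lfp, round(tri$end_s[i] * LFP_FS))
        c(band_power(welch_power(session$lfp$dCA1$samples[i0:i1]), "theta"),
          band_power(welch_power(session$lfp$mOFC$samples[i0:i1]), "theta"))
      }, numeric(2))
      list(block = b,
           theta_power_dCA1 = mean(tp[1, ]),
           theta_power_mOFC = mean(tp[2, ]),
           plv_theta = plv(th1$phase[idx], th2$phase[idx]),
           nm_1_5 = nm_plv(th1$phase[idx], lg2$phase[idx], 1, 5),
           mi_low_gamma = pac_mi(th1$phase[idx], lg2$amplitude[idx])$mi)
    })
    per_block[!vapply(per_block, is.null, logical(1))]
  })

  out$phase_locking <- stage("phase_locking", {
    cycles <- detect_theta_cycles(session$lfp$dCA1, sp_fun,
                                  swr_mask = if (!is.null(out$swr))
                                    out$swr$mask else NULL)
    th <- phase_series(session$lfp$dCA1$samples, "theta")
    pl <- lapply(session$units, theta_phase_locking, cycles = cycles,
                 theta_phase = th$phase)
    names(pl) <- vapply(session$units, `[[`, "", "unit_id")
    pl
  })

  out$pairs <- stage("pairs", {
    blocks <- block_windows(session$trials)
    pair_coordination(session$units, blocks, n_surr = n_surr,
                      master_seed = seed, swr_mask_fun = swr_mask_fun,
                      max_pairs = max_pairs)
  })

  out$assemblies <- stage("assemblies", {
    lw <- c(session$trials$start_s[1],
            session$trials$end_s[nrow(session$trials)])
    bz <- bin_and_zscore(session$units, lw,
                         swr_events = if (!is.null(out$swr))
                           out$swr$events else NULL)
    mp <- mp_significant_components(bz$z)
    pats <- extract_assemblies(bz$z, mp$n_significant, seed = seed)
    list(n_assemblies = mp$n_significant, patterns = pats,
         kept_units = bz$kept)
  })

  if (decode) out$decoding <- stage("decoding", {
    s <- build_samples(session$units, out$epochs, "stage", seed = seed)
    list(stage_auc = decode_auc(s)$auc)
  })

  out$status <- data.frame(stage = names(status),
                           ok = unlist(status), row.names = NULL)
  structure(out, class = "gs_session_summary")
}

#' Learning-block time windows from the trial table
#'
#' Blocks are consecutive runs of 10 trials; each block window spans from
#' the start of its first trial to the end of its last.
#'
#' @param trials Data frame with `start_s`, `end_s`.
#' @param block_size Trials per block.
#' @return Data frame with `block`, `start_s`, `end_s`.
#' @export
block_windows <- function(trials, block_size = 10) {
  nb <- ceiling(nrow(trials) / block_size)
  do.call(rbind, lapply(seq_len(nb), function(b) {
    idx <- ((b - 1) * block_size + 1):min(b * block_size, nrow(trials))
    data.frame(block = b, start_s = trials$start_s[idx[1]],
               end_s = trials$end_s[idx[length(idx)]])
  }))
}
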