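## End-to-end orchestration: simulate (or read) -> filter -> annotate ->
## home ranges -> selection analyses -> reports, from a single config.

pipeline_defaults <- function() {
  list(
    seed = 1L, out_dir = "owlmove_out",
    tracks = NULL, meta = NULL, habitat = NULL,
    simulate = list(n_birds = 4, n_nights = 2, patch_scale = 150,
                    region = c(0, 0, 4000, 4000),
                    night_start_h = 21.5, night_end_h = 5.5),
    stages = list(annotate = TRUE, home_range = TRUE, selection = TRUE,
                  ssf = TRUE, pathsf = TRUE, ordinate = TRUE),
    ssf = list(k = 100, interval = 30),
    pathsf = list(n_alt = 20, buffer = 20, radius = 1500),
    ordinate = list(k = 3, n_perm = 10000),
    log_level = "info")
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown config key: ", paste0(path, nm))
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

write_report <- function(df, path, cfg_hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# owlmove %s | config %s | seed %d",
                     as.character(utils::packageVersion("owlmove")),
                     cfg_hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

plog <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[owlmove] %s", paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — synthetic data generation
#' (or track/habitat input from disk), position filtering, kinematics,
#' behavioural annotation, home ranges, the three Manly selection
#' analyses (home range, roosting, perching), the hunting step-selection
#' function, the commuting path-selection function with type contrasts,
#' and the ordination of hunting coefficients — and writes one report
#' CSV per analysis into `out_dir`, each with a provenance header
#' (package version, config hash, seed).  All randomness derives from
#' the global seed via per-stage sub-seeds, so a rerun with the same
#' config reproduces every output exactly.
#'
#' @param config a config list, or the path to a YAML file with the same
#'   structure (see `pipeline_defaults` in the package sources for the
#'   full key set); unknown keys are rejected.
#' @return named character vector of report paths, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  ## hash the analytic part of the config (output location excluded)
  hcfg <- cfg; hcfg$out_dir <- NULL
  hstr <- as.numeric(utf8ToInt(paste(deparse(hcfg), collapse = "")))
  cfg_hash <- sprintf("%08x",
                      sum(hstr * seq_along(hstr)) %% .Machine$integer.max)
  seed <- as.integer(cfg$seed)
  if (!is.null(cfg$tracks)) {
    if (!file.exists(cfg$tracks)) stop("tracks file not found: ", cfg$tracks)
    if (is.null(cfg$habitat) || !file.exists(cfg$habitat))
      stop("habitat map not found: ", cfg$habitat %||% "<missing>")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- character(0)

  ## inputs: simulate unless tracks are given
  if (is.null(cfg$tracks)) {
    plog(cfg, "simulating landscape and tracks")
    sim <- cfg$simulate
    map <- generate_landscape(patch_scale = sim$patch_scale,
                              region = as.numeric(sim$region),
                              seed = derive_seed(seed, "landscape"))
    tc <- truth_config(night_start_h = sim$night_start_h,
                       night_end_h = sim$night_end_h)
    ds <- simulate_tracks(map, tc, n_birds = sim$n_birds,
                          n_nights = sim$n_nights,
                          seed = derive_seed(seed, "tracks"))
    tracks <- ds$tracks
  } else {
    tracks <- read_tracks(cfg$tracks, meta_path = cfg$meta)
    map <- read_habitat_geojson(cfg$habitat)
  }
  meta <- track_meta(tracks)

  plog(cfg, "filtering positions")
  fl <- filter_positions(tracks, region = map)
  tracks <- fl$tracks
  steps <- derive_kinematics(tracks)

  labels <- NULL
  if (isTRUE(cfg$stages$annotate)) {
    plog(cfg, "annotating behaviour")
    labels <- annotate_behaviour(steps)
    act <- activity_summary(tracks, steps, labels)
    reports["activity"] <- write_report(
      act, file.path(cfg$out_dir, "activity.csv"), cfg_hash, seed)
  }

  hrs <- NULL
  if (isTRUE(cfg$stages$home_range)) {
    plog(cfg, "estimating home ranges")
    ids <- unique(tracks$individual_id)
    hrs <- lapply(ids, function(id)
      estimate_home_range(tracks[tracks$individual_id == id, ]))
    names(hrs) <- ids
    hr_tab <- home_range_summary(tracks, map)
    reports["home_ranges"] <- write_report(
      hr_tab, file.path(cfg$out_dir, "home_ranges.csv"), cfg_hash, seed)
  }

  if (isTRUE(cfg$stages$selection) && !is.null(hrs) && !is.null(labels)) {
    plog(cfg, "selection ratios (home range / roost / perch)")
    ids <- names(hrs)
    hr_use <- lapply(ids, function(id)
      home_range_use(hrs[[id]], map, nest_of(tracks, id)))
    names(hr_use) <- ids
    reports["selection_homerange"] <- write_report(
      as.data.frame(manly_selection(hr_use)),
      file.path(cfg$out_dir, "selection_homerange.csv"), cfg_hash, seed)

    roosts <- roost_events(tracks)
    roost_use_l <- list()
    perch_use_l <- list()
    for (id in ids) {
      ev <- roosts[roosts$individual_id == id, , drop = FALSE]
      if (nrow(ev) > 0) roost_use_l[[id]] <- roost_use(ev, map, hrs[[id]])
      pe <- perch_events(steps[steps$individual_id == id, ],
                         labels[steps$individual_id == id, ],
                         map, nest_of(tracks, id))
      pu <- perch_use(pe, hrs[[id]], map)
      if (!is.null(pu)) perch_use_l[[id]] <- pu
    }
    if (length(roost_use_l) > 0)
      reports["selection_roost"] <- write_report(
        as.data.frame(manly_selection(roost_use_l)),
        file.path(cfg$out_dir, "selection_roost.csv"), cfg_hash, seed)
    if (length(perch_use_l) > 0)
      reports["selection_perch"] <- write_report(
        as.data.frame(manly_selection(perch_use_l)),
        file.path(cfg$out_dir, "selection_perch.csv"), cfg_hash, seed)
  }

  ssf_fits <- NULL
  if (isTRUE(cfg$stages$ssf) && !is.null(labels)) {
    plog(cfg, "step-selection function")
    thinned <- thin_to_interval(steps, interval = cfg$ssf$interval,
                                labels = labels, mode = "hunting")
    if (!is.null(thinned) && nrow(thinned) > 0) {
      cs <- ssf_choice_sets(thinned, map, K = cfg$ssf$k,
                            seed = derive_seed(seed, "ssf"))
      ssf_fits <- fit_ssf(cs)
      reports["ssf"] <- write_report(
        as.data.frame(ssf_fits$population),
        file.path(cfg$out_dir, "ssf.csv"), cfg_hash, seed)
    }
  }

  if (isTRUE(cfg$stages$pathsf) && !is.null(labels)) {
    plog(cfg, "path-selection function")
    typed <- list()
    for (id in unique(steps$individual_id)) {
      pp <- extract_commuting_paths(steps[steps$individual_id == id, ],
                                    labels[steps$individual_id == id, ])
      typed <- c(typed, classify_commuting(pp, nest_of(tracks, id)))
    }
    if (length(typed) > 0) {
      csum <- commuting_summary(typed)
      contrasts <- tryCatch(compare_types(csum), warning = function(w) NULL)
      reports["commuting_types"] <- write_report(
        contrasts %||% csum,
        file.path(cfg$out_dir, "commuting_types.csv"), cfg_hash, seed)
      pcs <- tryCatch(
        path_choice_sets(typed, map, n_alt = cfg$pathsf$n_alt,
                         radius = cfg$pathsf$radius,
                         buffer = cfg$pathsf$buffer,
                         seed = derive_seed(seed, "pathsf")),
        error = function(e) NULL)
      if (!is.null(pcs)) {
        pf <- fit_pathsf(pcs)
        reports["pathsf"] <- write_report(
          as.data.frame(pf$population),
          file.path(cfg$out_dir, "pathsf.csv"), cfg_hash, seed)
      }
    }
  }

  if (isTRUE(cfg$stages$ordinate) && !is.null(ssf_fits)) {
    plog(cfg, "ordination of hunting coefficients")
    cls <- setdiff(habitat_classes(), c("cereals", "roads", "settlements"))
    conv <- Filter(function(f) f$converged, ssf_fits$fits)
    if (length(conv) > cfg$ordinate$k + 1) {
      coefs <- t(vapply(conv, function(f)
        f$coefficients[cls], numeric(length(cls))))
      colnames(coefs) <- cls
      vars <- NULL
      if (!is.null(meta)) {
        mi <- match(names(conv), meta$individual_id)
        vars <- data.frame(
          date = as.numeric(as.Date(meta$deploy_date[mi])),
          sex = meta$sex[mi])
        vars <- vars[, vapply(vars, function(v)
          length(unique(v)) > 1, TRUE), drop = FALSE]
        if (ncol(vars) == 0) vars <- NULL
      }
      ord <- ordinate_selection(coefs, variables = vars,
                                k = cfg$ordinate$k,
                                n_perm = cfg$ordinate$n_perm,
                                seed = derive_seed(seed, "ordinate"))
      pts <- as.data.frame(ord$nmds$points)
      names(pts) <- paste0("NMDS", seq_len(ncol(pts)))
      pts <- cbind(individual_id = rownames(coefs), pts,
                   stress = ord$nmds$stress)
      reports["ordination"] <- write_report(
        pts, file.path(cfg$out_dir, "ordination.csv"), cfg_hash, seed)
      if (!is.null(ord$fit))
        reports["envfit"] <- write_report(
          ord$fit, file.path(cfg$out_dir, "envfit.csv"), cfg_hash, seed)
    }
  }

  plog(cfg, "done: ", length(reports), " report(s) in ", cfg$out_dir)
  invisible(reports)
}
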