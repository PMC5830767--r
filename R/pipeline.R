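# Orchestration of the two workflows: the neutron chain (spectral
# fitting with model selection -> dispersion assembly -> branch
# minima -> sample comparison, plus the elastic lamellar/in-plane
# summary) and the configuration-frame chain (rdf / apl / gauche /
# density / contacts). Reports are plain lists written as JSON + TSV;
# every stage failure marks the bundle partial and records its cause.

#' Read a run configuration file
#'
#' YAML key-value file; paths are interpreted relative to the file.
#'
#' @param path Path to a YAML configuration.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  cfg
}

stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  if (res$ok) {
    report$stages[[name]] <- list(status = "ok")
    report[[name]] <- res$value
  } else {
    report$stages[[name]] <- list(status = "failed", cause = res$error)
    report$partial <- TRUE
    message("stage '", name, "' failed: ", res$error)
  }
  report
}

as_scan_list <- function(x, kind) {
  if (inherits(x, "tas_scan")) return(list(x))
  if (is.character(x)) return(lapply(x, read_scan, kind = kind))
  lapply(x, function(s) if (inherits(s, "tas_scan")) s else read_scan(s, kind = kind))
}

#' Run the neutron analysis workflow for one or two samples
#'
#' Per sample: every constant-q scan is fitted with sequential F-test
#' model selection and every constant-E scan with a fixed peak count;
#' detected modes are collected into a dispersion, assigned to
#' branches, and each branch's minimum is fitted with the quadratic
#' model. If a reflectivity scan is supplied the lamellar summary
#' (d_z, SLD profile, d_HH) is computed with the configured phase
#' vector, and an in-plane scan yields q_T and the area per tail.
#' With two samples, every branch's (alpha, omega0) pair is compared
#' by the two-sample z procedure (reported raw and
#' Bonferroni-adjusted; the raw view is the default reading).
#'
#' @param config Named list (or [read_run_config()] output) with
#'   `samples` (named list; each entry may contain `constant_q`,
#'   `constant_E`, `reflectivity`, `inplane` as objects or file
#'   paths), and optionally `alpha` (0.025), `df_policy`
#'   (`"standard"`), `e_scan_peaks` (2), `anchors`, `fit_range`
#'   (`c(1, 2)`), `phases` (default `c(1,-1,-1,-1,-1,1,1,-1,1)`),
#'   `out_dir`, `seed`.
#' @return A report list of class `neutron_report`; written to
#'   `out_dir` as JSON/TSV when configured.
#' @export
run_neutron_workflow <- function(config) {
  cfg <- config
  alpha <- cfg$alpha %||% 0.025
  df_policy <- cfg$df_policy %||% "standard"
  k_e <- cfg$e_scan_peaks %||% 2L
  anchors <- cfg$anchors %||% default_branch_anchors()
  fit_range <- cfg$fit_range %||% c(1.0, 2.0)
  phases <- cfg$phases %||% c(1, -1, -1, -1, -1, 1, 1, -1, 1)
  if (is.null(cfg$samples) || !length(cfg$samples))
    stop("config$samples must name at least one sample")
  for (sm in cfg$samples) {
    for (fld in c("constant_q", "constant_E", "reflectivity", "inplane")) {
      if (is.character(sm[[fld]]) && !all(file.exists(sm[[fld]])))
        stop("missing input file(s): ",
             paste(sm[[fld]][!file.exists(sm[[fld]])], collapse = ", "))
    }
  }
  report <- list(workflow = "neutron", partial = FALSE, stages = list(),
                 seed = cfg$seed %||% NA, samples = list())
  for (name in names(cfg$samples)) {
    sm <- cfg$samples[[name]]
    sub <- list(stages = list(), partial = FALSE)
    sub <- stage(sub, "spectral_fits", {
      fits <- list()
      selections <- list()
      for (scan in as_scan_list(sm$constant_q %||% list(), "constant_q")) {
        sel <- sequential_f_test(scan, alpha = alpha, df_policy = df_policy)
        selections[[length(selections) + 1L]] <- sel
        fits[[length(fits) + 1L]] <- sel$fits[[sel$chosen_k]]
      }
      for (scan in as_scan_list(sm$constant_E %||% list(), "constant_E"))
        fits[[length(fits) + 1L]] <- fit_constant_e_scan(scan, k = k_e)
      list(fits = fits, selections = selections)
    })
    if (!is.null(sub$spectral_fits)) {
      sub <- stage(sub, "dispersion", {
        pts <- collect_points(sub$spectral_fits$fits)
        assign_branches(pts, anchors = anchors)
      })
    }
    if (!is.null(sub$dispersion)) {
      sub <- stage(sub, "branch_fits", {
        out <- list()
        for (br in setdiff(unique(sub$dispersion$branch), "unassigned")) {
          n_in <- sum(sub$dispersion$branch == br &
                        sub$dispersion$q_par >= fit_range[1L] &
                        sub$dispersion$q_par <= fit_range[2L])
          if (n_in >= 4L)
            out[[br]] <- fit_branch_minimum(sub$dispersion,
                                            fit_range = fit_range, branch = br)
        }
        out
      })
    }
    if (!is.null(sm$reflectivity)) {
      sub <- stage(sub, "lamellar", {
        rs <- if (inherits(sm$reflectivity, "refl_scan")) sm$reflectivity
        else read_reflectivity(sm$reflectivity)
        pk <- find_bragg_peaks(rs)
        sld <- reconstruct_sld(pk, phases)
        dhh <- head_head_spacing(sld)
        list(peaks = pk$peaks, d_z = pk$d_z, d_HH = as.numeric(dhh),
             sld = data.frame(z = sld$z, rho = sld$rho))
      })
    }
    if (!is.null(sm$inplane)) {
      sub <- stage(sub, "inplane", {
        sc <- if (inherits(sm$inplane, "refl_scan") ||
                  inherits(sm$inplane, "tas_scan")) sm$inplane
        else read_reflectivity(sm$inplane)
        find_inplane_peak(sc)
      })
    }
    report$partial <- report$partial || sub$partial
    report$samples[[name]] <- sub
  }
  if (length(report$samples) == 2L) {
    report <- stage(report, "comparison", {
      nm <- names(report$samples)
      fa <- report$samples[[1L]]$branch_fits
      fb <- report$samples[[2L]]$branch_fits
      rows <- list()
      for (br in intersect(names(fa), names(fb))) {
        cmp <- compare_branch_parameters(fa[[br]], fb[[br]])
        cmp <- cmp[cmp$parameter %in% c("alpha", "omega0"), ]
        cmp$branch <- br
        rows[[br]] <- cmp
      }
      cmp <- do.call(rbind, rows)
      rownames(cmp) <- NULL
      n_tests <- nrow(cmp)
      cmp$p_raw <- 2 * stats::pnorm(-cmp$z)
      cmp$p_bonferroni <- pmin(1, cmp$p_raw * n_tests)
      cmp$significant_bonferroni <- cmp$p_bonferroni < 0.05
      list(samples = nm, table = cmp)
    })
  }
  class(report) <- "neutron_report"
  if (!is.null(cfg$out_dir)) write_neutron_report(report, cfg$out_dir)
  report
}

write_neutron_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (name in names(report$samples)) {
    sub <- report$samples[[name]]
    if (!is.null(sub$dispersion)) {
      f <- file.path(out_dir, paste0(name, "_dispersion.tsv"))
      utils::write.table(as.data.frame(sub$dispersion), f, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    if (!is.null(sub$lamellar)) {
      f <- file.path(out_dir, paste0(name, "_sld.tsv"))
      utils::write.table(sub$lamellar$sld, f, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
  }
  json <- file.path(out_dir, "neutron_report.json")
  jsonlite::write_json(report_summary(report), json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, json))
}

report_summary <- function(report) {
  out <- list(workflow = report$workflow, partial = report$partial,
              seed = report$seed, samples = list())
  for (name in names(report$samples)) {
    sub <- report$samples[[name]]
    s <- list(stages = sub$stages)
    if (!is.null(sub$branch_fits))
      s$branch_parameters <- lapply(sub$branch_fits, function(bf)
        list(alpha = bf$alpha, alpha_se = unname(bf$std_errors["alpha"]),
             q0 = bf$q0, q0_se = unname(bf$std_errors["q0"]),
             omega0 = bf$omega0,
             omega0_se = unname(bf$std_errors["omega0"])))
    if (!is.null(sub$lamellar))
      s$elastic <- list(d_z = sub$lamellar$d_z, d_HH = sub$lamellar$d_HH)
    if (!is.null(sub$inplane))
      s$inplane <- list(q_T = sub$inplane$q_T, A_T = sub$inplane$A_T)
    out$samples[[name]] <- s
  }
  if (!is.null(report$comparison)) out$comparison <- report$comparison$table
  out
}

#' Run the configuration-frame analysis workflow
#'
#' Executes the requested lateral-organization tasks on a set of
#' membrane frames. Tasks needing the drug (`gauche` radial profile,
#' drug-centred `apl` profile, `contacts`) are skipped with a recorded
#' cause when no ASA residues are present.
#'
#' @param config Named list: `frames` (list of [membrane_frame]s or
#'   file paths), `tasks` (subset of `"rdf"`, `"apl"`, `"gauche"`,
#'   `"density"`, `"contacts"`; default all), plus optional task
#'   parameters `rdf_r_max` (20), `rdf_bin` (0.2), `bins`
#'   (`seq(0, 30, 2)`), `stride` (50), `cutoff` (3.5),
#'   `deuteration_map`, `out_dir`.
#' @return A report list of class `md_report`.
#' @export
run_md_workflow <- function(config) {
  cfg <- config
  frames <- cfg$frames
  if (is.character(frames)) frames <- read_frames(frames)
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  if (!length(frames)) stop("no frames supplied")
  tasks <- cfg$tasks %||% c("rdf", "apl", "gauche", "density", "contacts")
  bins <- cfg$bins %||% seq(0, 30, by = 2)
  has_asa <- any(frames[[1L]]$res_names == "ASA")
  report <- list(workflow = "md", partial = FALSE, stages = list(),
                 n_frames = length(frames))
  if ("rdf" %in% tasks) {
    report <- stage(report, "rdf", {
      r_max <- min(cfg$rdf_r_max %||% 20,
                   min(frames[[1L]]$box[1:2]) / 2 - 0.5)
      out <- list(dmpc_dmpc = lateral_rdf(
        frames, list(resname = "DMPC", name = "^C[12]A$"),
        list(resname = "DMPC", name = "^C[12]A$"),
        r_max = r_max, bin_width = cfg$rdf_bin %||% 0.2))
      if (has_asa) {
        out$chol_asa <- lateral_rdf(frames, list(resname = "CHOL"),
                                    list(resname = "ASA"), r_max = r_max,
                                    bin_width = cfg$rdf_bin %||% 0.5)
        out$asa_asa <- lateral_rdf(frames, list(resname = "ASA"),
                                   list(resname = "ASA"), r_max = r_max,
                                   bin_width = cfg$rdf_bin %||% 0.5)
      }
      out
    })
  }
  if ("apl" %in% tasks) {
    report <- stage(report, "apl", {
      maps <- lapply(frames, grid_area_map)
      mean_area <- mean(unlist(lapply(maps, function(m) lipid_areas(m)$area)))
      out <- list(mean_dmpc_area = mean_area)
      if (has_asa) out$by_distance <- distance_resolved_area(frames, bins = bins)
      out
    })
  }
  if ("gauche" %in% tasks) {
    if (has_asa) {
      report <- stage(report, "gauche",
                      distance_resolved_gauche(frames, bins = bins,
                                               stride = cfg$stride %||% 50L))
    } else {
      report$stages$gauche <- list(status = "skipped",
                                   cause = "no ASA residues in frames")
    }
  }
  if ("density" %in% tasks) {
    report <- stage(report, "density", {
      groups <- list(DMPC = list(resname = "DMPC"),
                     CHOL = list(resname = "CHOL"))
      if (has_asa) groups$ASA <- list(resname = "ASA")
      if (any(frames[[1L]]$res_names == "SOL"))
        groups$SOL <- list(resname = "SOL")
      list(electron = density_profile(frames, groups, "electron"),
           neutron = density_profile(frames, groups, "neutron_sl",
                                     deuteration_map = cfg$deuteration_map))
    })
  }
  if ("contacts" %in% tasks) {
    if (has_asa) {
      report <- stage(report, "contacts",
                      contact_fraction(frames, list(resname = "CHOL"),
                                       list(resname = "ASA"),
                                       cutoff = cfg$cutoff %||% 3.5))
    } else {
      report$stages$contacts <- list(status = "skipped",
                                     cause = "no ASA residues in frames")
    }
  }
  class(report) <- "md_report"
  if (!is.null(cfg$out_dir)) write_md_report(report, cfg$out_dir)
  report
}

write_md_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, f) {
    utils::write.table(df, file.path(out_dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$rdf))
    for (nm in names(report$rdf))
      wtsv(data.frame(r = report$rdf[[nm]]$r, g = report$rdf[[nm]]$g),
           paste0("rdf_", nm, ".tsv"))
  if (!is.null(report$apl$by_distance))
    wtsv(as.data.frame(report$apl$by_distance), "area_by_distance.tsv")
  if (!is.null(report$gauche))
    wtsv(as.data.frame(report$gauche), "gauche_by_distance.tsv")
  if (!is.null(report$density))
    for (nm in names(report$density))
      wtsv(data.frame(z = report$density[[nm]]$z,
                      report$density[[nm]]$density),
           paste0("density_", nm, ".tsv"))
  summ <- list(workflow = "md", partial = report$partial,
               stages = report$stages, n_frames = report$n_frames)
  if (!is.null(report$apl)) summ$mean_dmpc_area <- report$apl$mean_dmpc_area
  if (!is.null(report$contacts))
    summ$contact_pairs <- nrow(report$contacts$pairs)
  jsonlite::write_json(summ, file.path(out_dir, "md_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
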