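#' Generate a synthetic longitudinal AD/MCI cohort
#'
#' Draws static patient features and per-visit neuropsychological scales at
#' months 0, 3 and 6. The ADAS-cog trajectory is the causal backbone:
#' `ADAS(t) = ADAS(0) + (t/3) * drift(arm) + eta_t`, where `eta` is AR(1)
#' noise across visits (coefficient `spec$ar1`, marginal sd `spec$noise_sd`).
#' Secondary scales move with the patient's ADAS-cog change through the
#' schema's coupling coefficients plus independent residual noise, so that a
#' treatment that improves cognition also shifts the secondary instruments in
#' the clinically expected direction. The diagnosis class is MCI when the
#' baseline MMSE is at or above `spec$mci_mmse_cutoff`, else AD.
#'
#' All scale values are clipped to their instrument ranges after generation;
#' the number of clipped cells per feature is recorded in the `clipped`
#' attribute of the result.
#'
#' @param spec A [cohort_spec()].
#' @param schema A [default_schema()] (or a modified copy).
#' @return A `cohort_table`: a data.frame with one row per patient per
#'   scheduled visit, columns `id`, `month`, `diagnosis`, the static features
#'   (repeated across a patient's visits) and the time-dependent scales.
#' @export
#' @examples
#' tab <- generate_cohort(cohort_spec(n_patients = 20, seed = 1))
#' table(tab$month)
generate_cohort <- function(spec, schema = default_schema()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  months <- schema$months
  cols <- cohort_columns(schema)
  if (n == 0) {
    empty <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(empty) <- cols
    return(structure(empty, class = c("cohort_table", "data.frame"),
                     schema = schema, clipped = integer(0)))
  }

  with_seed(spec$seed, {
    clipped <- c()
    draw_marginal <- function(m, s, lo, hi, dist, n) {
      if (dist == "gamma") {
        shape <- (m / s)^2
        rate <- m / s^2
        x <- rgamma(n, shape = shape, rate = rate)
      } else {
        mu <- calibrate_clip_location(m, s, lo, hi)
        x <- rnorm(n, mu, s)
      }
      n_clip <- sum(x < lo | x > hi)
      list(x = clip(x, lo, hi), n_clip = n_clip)
    }

    arm <- sample(names(spec$arm_probs), n, replace = TRUE,
                  prob = spec$arm_probs)
    gprobs <- schema$gender$probs
    if (!spec$female_majority) gprobs <- rev(gprobs)
    gender <- sample(schema$gender$levels, n, replace = TRUE, prob = gprobs)

    static <- data.frame(id = seq_len(n))
    sc <- schema$static_continuous
    for (i in seq_len(nrow(sc))) {
      d <- draw_marginal(sc$mean[i], sc$sd[i], sc$lo[i], sc$hi[i],
                         sc$dist[i], n)
      static[[sc$name[i]]] <- d$x
      clipped[sc$name[i]] <- d$n_clip
    }
    sb <- schema$static_binary
    for (i in seq_len(nrow(sb))) {
      static[[sb$name[i]]] <- rbinom(n, 1L, sb$prob[i])
    }
    static$gender <- gender
    static$arm <- arm

    td <- schema$time_dependent
    base <- matrix(NA_real_, n, nrow(td), dimnames = list(NULL, td$name))
    for (i in seq_len(nrow(td))) {
      d <- draw_marginal(td$mean[i], td$sd[i], td$lo[i], td$hi[i],
                         td$dist[i], n)
      base[, i] <- d$x
      clipped[td$name[i]] <- d$n_clip
    }

    # ADAS-cog trajectory: AR(1) deviations with stationary marginal sd.
    drift <- spec$drift[arm]
    eta3 <- spec$noise_sd * rnorm(n)
    eta6 <- spec$ar1 * eta3 +
      spec$noise_sd * sqrt(1 - spec$ar1^2) * rnorm(n)
    adas_idx <- match("adas_cog", td$name)
    adas <- cbind(base[, adas_idx],
                  base[, adas_idx] + drift + eta3,
                  base[, adas_idx] + 2 * drift + eta6)
    n_clip_adas <- sum(adas < td$lo[adas_idx] | adas > td$hi[adas_idx])
    clipped["adas_cog"] <- clipped["adas_cog"] + n_clip_adas
    adas <- clip(adas, td$lo[adas_idx], td$hi[adas_idx])
    adas_change <- adas - adas[, 1]  # n x 3, column per visit

    diagnosis <- ifelse(base[, match("mmse", td$name)] >= spec$mci_mmse_cutoff,
                        "MCI", "AD")

    rows <- vector("list", length(months))
    for (v in seq_along(months)) {
      vals <- data.frame(id = seq_len(n), month = months[v],
                         diagnosis = diagnosis)
      vals <- cbind(vals, static[, -1, drop = FALSE])
      for (i in seq_len(nrow(td))) {
        nm <- td$name[i]
        if (nm == "adas_cog") {
          vals[[nm]] <- adas[, v]
        } else if (months[v] == 0) {
          vals[[nm]] <- base[, i]
        } else {
          resid <- spec$resid_frac * td$sd[i] * rnorm(n)
          x <- base[, i] +
            td$coupling[i] * (td$sd[i] / td$sd[adas_idx]) * adas_change[, v] +
            resid
          clipped[nm] <- clipped[nm] + sum(x < td$lo[i] | x > td$hi[i])
          vals[[nm]] <- clip(x, td$lo[i], td$hi[i])
        }
      }
      rows[[v]] <- vals
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$id, out$month), cols]
    rownames(out) <- NULL
    structure(out, class = c("cohort_table", "data.frame"),
              schema = schema, clipped = clipped)
  })
}

#' Set cohort cells missing at random
#'
#' Independently blanks each eligible cell with its feature's missingness
#' rate. Static features are blanked at the patient level (a missing static
#' value is missing at every visit). The baseline ADAS-cog is never removed,
#' so the conversion label reference always exists.
#'
#' @param table A `cohort_table`.
#' @param spec The [cohort_spec()] carrying `miss_rate` (single rate or named
#'   per-feature vector) and the seed (offset internally so missingness draws
#'   do not reuse the generator's stream).
#' @return The table with `NA` cells injected.
#' @export
inject_missingness <- function(table, spec) {
  schema <- attr(table, "schema") %||% default_schema()
  rates <- spec$miss_rate
  feats <- feature_names(schema)
  if (is.null(names(rates))) {
    rates <- stats::setNames(rep(rates[1], length(feats)), feats)
  } else {
    unknown <- setdiff(names(rates), feats)
    if (length(unknown)) stopf("unknown feature in miss_rate: %s", unknown[1])
    full <- stats::setNames(rep(0, length(feats)), feats)
    full[names(rates)] <- rates
    rates <- full
  }
  if (nrow(table) == 0 || all(rates == 0)) return(table)
  with_seed(spec$seed + 1000003L, {
    ids <- unique(table$id)
    statics <- static_feature_names(schema)
    for (f in feats) {
      r <- rates[[f]]
      if (r == 0) next
      if (f %in% statics) {
        drop_ids <- ids[runif(length(ids)) < r]
        table[[f]][table$id %in% drop_ids] <- NA
      } else {
        hit <- runif(nrow(table)) < r
        if (f == "adas_cog") hit <- hit & table$month != 0
        table[[f]][hit] <- NA
      }
    }
    table
  })
}

#' Write / read a cohort table as delimited text
#'
#' The on-disk format is UTF-8 CSV with one row per patient-visit and empty
#' fields for missing values, plus a sidecar JSON file (`<path>.schema.json`)
#' listing each feature's kind so a round trip restores column types.
#'
#' @param table A `cohort_table`.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   `cohort_table`.
#' @export
write_cohort <- function(table, path) {
  schema <- attr(table, "schema") %||% default_schema()
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  kinds <- c(
    stats::setNames(rep("continuous", nrow(schema$static_continuous)),
                    schema$static_continuous$name),
    stats::setNames(rep("binary", nrow(schema$static_binary)),
                    schema$static_binary$name),
    gender = "categorical", arm = "categorical",
    stats::setNames(rep("continuous", nrow(schema$time_dependent)),
                    schema$time_dependent$name)
  )
  jsonlite::write_json(list(columns = cohort_columns(schema),
                            kinds = as.list(kinds),
                            months = schema$months),
                       paste0(path, ".schema.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @param schema Feature schema the file must conform to.
#' @export
read_cohort <- function(path, schema = default_schema()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  cols <- cohort_columns(schema)
  unknown <- setdiff(names(raw), cols)
  if (length(unknown)) {
    stopf("unknown column in cohort file '%s': %s", path, unknown[1])
  }
  miss <- setdiff(cols, names(raw))
  if (length(miss)) {
    stopf("cohort file '%s' is missing column: %s", path, miss[1])
  }
  bad <- which(!(raw$month %in% schema$months))
  if (length(bad)) {
    stopf("cohort file '%s', row %d, column 'month': %s is not a scheduled visit",
          path, bad[1], raw$month[bad[1]])
  }
  raw <- raw[order(raw$id, raw$month), cols]
  rownames(raw) <- NULL
  structure(raw, class = c("cohort_table", "data.frame"), schema = schema)
}
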