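#' Configuration for the synthetic high-content screen
#'
#' Describes a plate-based siRNA screen in which each library target occupies
#' one well on one plate, every plate carries non-targeting (nt) negative
#' controls and positive controls, and the whole layout is transfected in
#' replicate. Well-level feature vectors are composed as
#' class archetype + plate offset + Gaussian noise, mimicking the structure a
#' plate Z-score normalization is designed to remove.
#'
#' Targets are planted into `n_classes` phenotype classes. The first five
#' classes follow named archetypes over feature groups (intensity, size,
#' symmetry, texture):
#' \describe{
#'   \item{normal}{no deviation; nt controls belong here.}
#'   \item{enhanced}{higher marker intensity, size and symmetry — the
#'     phenotype of silencing a reprogramming roadblock (role `blocker`),
#'     shared with the Trp53 positive control.}
#'   \item{blocked}{low marker intensity and size — the phenotype of
#'     silencing a reprogramming facilitator (role `facilitator`), shared
#'     with the Myc and Oct4 positive controls.}
#'   \item{irregular}{asymmetric colonies with altered texture.}
#'   \item{dense}{small, texture-shifted colonies.}
#' }
#' Classes beyond the fifth receive random sign archetypes drawn from `seed`.
#'
#' @param n_plates Number of library plates (default 6).
#' @param wells_per_plate Wells per plate (default 96).
#' @param n_replicates Replicate transfections of the whole layout (default 4).
#' @param n_targets Number of library genes (default 300).
#' @param n_nt_controls_per_plate Non-targeting control wells per plate
#'   (default 7).
#' @param positive_controls Labels of positive-control siRNAs present on every
#'   plate (default `c("Trp53", "Myc", "Oct4")`).
#' @param n_features Number of extracted colony features (default 40).
#' @param n_classes Number of planted phenotype classes (default 5).
#' @param class_effect_size Archetype magnitude in feature-SD units
#'   (default 3).
#' @param plate_effect_sd SD of the additive per-plate, per-replicate,
#'   per-feature batch offset (default 0.5).
#' @param noise_sd SD of the well-level Gaussian noise (default 1).
#' @param archetype_jitter Per-feature SD of the class archetypes around
#'   their group-level pattern, as a fraction of `class_effect_size`
#'   (default 0.5); keeps features within a group correlated without being
#'   duplicates.
#' @param class_weights Sampling weights of the classes for library targets;
#'   default concentrates mass on the normal class as most knockdowns are
#'   phenotypically silent.
#' @param seed Integer seed; the same config and seed reproduce the tables
#'   exactly.
#' @return An object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_plates = 6, wells_per_plate = 96,
                              n_replicates = 4, n_targets = 300,
                              n_nt_controls_per_plate = 7,
                              positive_controls = c("Trp53", "Myc", "Oct4"),
                              n_features = 40, n_classes = 5,
                              class_effect_size = 3, plate_effect_sd = 0.5,
                              noise_sd = 1, archetype_jitter = 0.5,
                              class_weights = NULL, seed = 1) {
  cfg <- list(
    n_plates = check_count(n_plates, "n_plates"),
    wells_per_plate = check_count(wells_per_plate, "wells_per_plate", min = 3L),
    n_replicates = check_count(n_replicates, "n_replicates"),
    n_targets = check_count(n_targets, "n_targets"),
    n_nt_controls_per_plate = check_count(n_nt_controls_per_plate,
                                          "n_nt_controls_per_plate", min = 0L),
    positive_controls = as.character(positive_controls),
    n_features = check_count(n_features, "n_features", min = 2L),
    n_classes = check_count(n_classes, "n_classes", min = 2L),
    class_effect_size = check_positive(class_effect_size, "class_effect_size"),
    plate_effect_sd = check_positive(plate_effect_sd, "plate_effect_sd",
                                     strict = FALSE),
    noise_sd = check_positive(noise_sd, "noise_sd", strict = FALSE),
    archetype_jitter = check_positive(archetype_jitter, "archetype_jitter",
                                      strict = FALSE),
    seed = check_count(seed, "seed", min = 0L)
  )
  k <- cfg$n_classes
  if (is.null(class_weights)) {
    class_weights <- if (k >= 5) {
      c(0.47, 0.12, 0.06, 0.20, 0.15, rep(0.05, k - 5))
    } else {
      c(0.5, rep(0.5 / (k - 1), k - 1))
    }
  }
  if (length(class_weights) != k || any(class_weights <= 0)) {
    stop("'class_weights' must hold one positive weight per class",
         call. = FALSE)
  }
  cfg$class_weights <- class_weights / sum(class_weights)
  per_plate <- ceiling(cfg$n_targets / cfg$n_plates)
  n_ctrl <- cfg$n_nt_controls_per_plate + length(cfg$positive_controls)
  if (per_plate + n_ctrl > cfg$wells_per_plate) {
    stop(sprintf(
      "layout infeasible: %d targets/plate + %d control wells exceed %d wells",
      per_plate, n_ctrl, cfg$wells_per_plate), call. = FALSE)
  }
  structure(cfg, class = "screen_sim_config")
}

# Feature names grouped by the kind of colony descriptor they emulate.
screen_feature_names <- function(n_features) {
  groups <- rep(c("intensity", "size", "symmetry", "texture", "texture"),
                length.out = n_features)
  idx <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  list(names = sprintf("feature_%s_%02d", groups, idx), groups = groups)
}

# Archetype matrix (n_classes x n_features) in feature-SD units before
# scaling; row 1 is the all-zero "normal" class. Each non-normal class adds
# per-feature jitter around its group-level sign pattern so that features in
# a group are correlated without being duplicates, as in real feature sets.
screen_archetypes <- function(n_classes, groups, effect, jitter = 0.5) {
  canon <- list(
    normal    = c(intensity = 0, size = 0, symmetry = 0, texture = 0),
    enhanced  = c(intensity = 1, size = 1, symmetry = 1, texture = 0),
    blocked   = c(intensity = -1, size = -1, symmetry = 0, texture = 0),
    irregular = c(intensity = 0, size = 0, symmetry = -1, texture = 1),
    dense     = c(intensity = 0, size = -1, symmetry = 0, texture = -1)
  )
  a <- matrix(0, n_classes, length(groups))
  nm <- character(n_classes)
  for (cl in seq_len(n_classes)) {
    if (cl <= length(canon)) {
      a[cl, ] <- canon[[cl]][groups] * effect
      nm[cl] <- names(canon)[cl]
      if (cl > 1) {
        a[cl, ] <- a[cl, ] +
          stats::rnorm(length(groups), sd = jitter * effect)
      }
    } else {
      # extra classes: random sign pattern per feature group
      sgn <- sample(c(-1, 0, 1), length(unique(groups)), replace = TRUE)
      names(sgn) <- unique(groups)
      a[cl, ] <- sgn[groups] * effect +
        stats::rnorm(length(groups), sd = jitter * effect)
      nm[cl] <- sprintf("class_%d", cl)
    }
  }
  rownames(a) <- nm
  a
}

#' Simulate a plate-based high-content siRNA screen
#'
#' Generates per-well colony-feature tables for every plate and replicate,
#' plus a ground-truth table of planted phenotype classes and gene roles for
#' parameter-recovery testing. Each well's feature vector is the sum of its
#' target's class archetype, an additive plate (batch) offset shared by all
#' wells of a physical plate, and independent Gaussian noise. Controls are
#' placed on every plate: nt controls carry the normal archetype, Trp53 the
#' enhanced archetype, and Myc/Oct4 the blocked archetype. The well layout is
#' drawn once and reused across replicates, as in a replicated transfection
#' of a fixed library layout.
#'
#' @param config A [screen_sim_config()].
#' @return A list of class `screen_sim` with elements
#'   \describe{
#'     \item{tables}{long data frame with columns `plate`, `replicate`,
#'       `well`, `target`, `role` (`nt` / `positive` / `library`) and
#'       `feature_*` columns.}
#'     \item{truth}{data frame `target`, `class` (integer), `class_name`,
#'       `role` (`facilitator` / `blocker` / `neutral`), `is_control`.}
#'     \item{archetypes}{class-by-feature archetype matrix.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' sim <- generate_screen(screen_sim_config(n_targets = 24, n_plates = 2,
#'                                          n_replicates = 2, seed = 7))
#' head(sim$tables[, 1:6])
#' table(sim$truth$class_name)
generate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    feat <- screen_feature_names(config$n_features)
    arch <- screen_archetypes(config$n_classes, feat$groups,
                              config$class_effect_size,
                              jitter = config$archetype_jitter)

    targets <- sprintf("gene_%03d", seq_len(config$n_targets))
    cls <- sample(seq_len(config$n_classes), config$n_targets, replace = TRUE,
                  prob = config$class_weights)
    role <- rep("neutral", config$n_targets)
    role[rownames(arch)[cls] == "blocked"] <- "facilitator"
    role[rownames(arch)[cls] == "enhanced"] <- "blocker"

    nt_labels <- if (config$n_nt_controls_per_plate > 0) {
      sprintf("nt_%02d", seq_len(config$n_nt_controls_per_plate))
    } else {
      character(0)
    }
    pc_labels <- config$positive_controls
    pc_class <- vapply(pc_labels, function(p) {
      if (p == "Trp53") min(2L, config$n_classes) else min(3L, config$n_classes)
    }, integer(1))

    truth <- data.frame(
      target = c(targets, nt_labels, pc_labels),
      class = c(cls, rep(1L, length(nt_labels)), pc_class),
      stringsAsFactors = FALSE
    )
    truth$class_name <- rownames(arch)[truth$class]
    truth$role <- c(role, rep("neutral", length(nt_labels)),
                    ifelse(rownames(arch)[pc_class] == "blocked",
                           "facilitator", "blocker"))
    truth$is_control <- truth$target %in% c(nt_labels, pc_labels)
    rownames(truth) <- NULL

    # plate layout: contiguous blocks of library targets, fixed across
    # replicates; controls interleaved at random well positions
    per_plate <- ceiling(config$n_targets / config$n_plates)
    n_rows <- ceiling(config$wells_per_plate / 12)
    well_ids <- sprintf("%s%02d", rep(LETTERS[seq_len(n_rows)], each = 12),
                        rep(1:12, n_rows))[seq_len(config$wells_per_plate)]

    layout <- vector("list", config$n_plates)
    for (p in seq_len(config$n_plates)) {
      idx <- seq((p - 1) * per_plate + 1, min(p * per_plate, config$n_targets))
      plate_targets <- c(targets[idx], nt_labels, pc_labels)
      plate_roles <- c(rep("library", length(idx)),
                       rep("nt", length(nt_labels)),
                       rep("positive", length(pc_labels)))
      pos <- sample(config$wells_per_plate, length(plate_targets))
      ord <- order(pos)
      layout[[p]] <- data.frame(
        plate = sprintf("plate_%d", p),
        well = well_ids[pos[ord]],
        target = plate_targets[ord],
        role = plate_roles[ord],
        stringsAsFactors = FALSE
      )
    }
    layout <- do.call(rbind, layout)

    class_of <- truth$class[match(layout$target, truth$target)]
    n_well <- nrow(layout)

    out <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      plate_offset <- matrix(
        stats::rnorm(config$n_plates * config$n_features,
                     sd = config$plate_effect_sd),
        config$n_plates, config$n_features)
      plate_idx <- as.integer(factor(layout$plate,
                                     levels = sprintf("plate_%d",
                                                      seq_len(config$n_plates))))
      values <- arch[class_of, , drop = FALSE] +
        plate_offset[plate_idx, , drop = FALSE] +
        matrix(stats::rnorm(n_well * config$n_features, sd = config$noise_sd),
               n_well, config$n_features)
      colnames(values) <- feat$names
      out[[r]] <- cbind(
        data.frame(plate = layout$plate, replicate = r, well = layout$well,
                   target = layout$target, role = layout$role,
                   stringsAsFactors = FALSE),
        as.data.frame(values)
      )
    }
    tables <- do.call(rbind, out)
    rownames(tables) <- NULL

    structure(list(tables = tables, truth = truth, archetypes = arch,
                   config = config),
              class = "screen_sim")
  })
}
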