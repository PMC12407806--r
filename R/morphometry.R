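# Closed-form calculators used in the experimental validation of the
# atlas-derived predictions (muscle, heart, fat body, qPCR). All are pure
# and total on their stated domains; units are the caller's responsibility
# but must be consistent within a call.

#' Flight-muscle volume from a longitudinal section
#'
#' Adult flight muscles are too thick to image entirely, so volume is
#' estimated as longitudinal surface area times muscle thickness (depth for
#' pupal muscles): \code{volume = area * thickness}. With area in um^2 and
#' thickness in um the volume is in um^3.
#'
#' @param area longitudinal section area (> 0).
#' @param thickness muscle thickness or depth (> 0).
#' @return the volume estimate.
#' @examples
#' muscleVolume(1000, 50)  # 50000 um^3
#' @export
muscleVolume <- function(area, thickness) {
    if (any(area <= 0) || any(thickness <= 0))
        stop("area and thickness must be > 0")
    area * thickness
}

#' Extrapolate a nuclei count from an analyzed sub-volume
#'
#' Nuclei are counted in a fixed imaging volume and, assuming uniform
#' nuclear distribution, scaled to the whole muscle:
#' \code{total = totalVolume / analyzedVolume * counted}.
#'
#' @param totalVolume total muscle volume (>= \code{analyzedVolume}).
#' @param analyzedVolume imaged volume in the same units (> 0).
#' @param counted nuclei counted in the analyzed volume (>= 0).
#' @return extrapolated total nuclei (real-valued).
#' @examples
#' extrapolateNuclei(10, 1, 100)  # 1000
#' @export
extrapolateNuclei <- function(totalVolume, analyzedVolume, counted) {
    if (any(analyzedVolume <= 0)) stop("analyzedVolume must be > 0")
    if (any(totalVolume < analyzedVolume))
        stop("totalVolume must be >= analyzedVolume")
    if (any(counted < 0)) stop("counted must be >= 0")
    totalVolume / analyzedVolume * counted
}

#' Nuclear density
#'
#' @param count nuclei count (>= 0).
#' @param volume muscle volume (> 0).
#' @return nuclei per unit volume.
#' @export
nuclearDensity <- function(count, volume) {
    if (any(volume <= 0)) stop("volume must be > 0")
    if (any(count < 0)) stop("count must be >= 0")
    count / volume
}

#' Cardiac fractional shortening
#'
#' Contractility index from end-diastolic and end-systolic heart-chamber
#' diameters: \code{FS = (EDD - ESD) * 100 / EDD}, in percent. Scale
#' invariant (any consistent length unit).
#'
#' @param EDD end-diastolic diameter (> 0).
#' @param ESD end-systolic diameter, \code{0 <= ESD <= EDD}.
#' @return FS in [0, 100].
#' @examples
#' fractionalShortening(80, 56)  # 30
#' @export
fractionalShortening <- function(EDD, ESD) {
    if (any(EDD <= 0)) stop("EDD must be > 0")
    if (any(ESD < 0) || any(ESD > EDD))
        stop("need 0 <= ESD <= EDD (diastolic diameter is the larger)")
    (EDD - ESD) * 100 / EDD
}

#' Geometric stroke volume from chamber diameters
#'
#' Volume ejected per beat under a cylindrical chamber model:
#' \code{SV = pi/4 * (EDD^2 - ESD^2) * chamberLength}. The model name is
#' recorded on the result; between-sex ratios are robust to the choice of
#' geometry at fixed chamber length.
#'
#' @param EDD,ESD diameters as in \code{\link{fractionalShortening}}.
#' @param chamberLength measured chamber length (> 0).
#' @param model only \code{"cylindrical"} is implemented.
#' @return stroke volume, with attribute \code{model}.
#' @examples
#' strokeVolume(2, 0, 1)  # pi
#' @export
strokeVolume <- function(EDD, ESD, chamberLength, model = "cylindrical") {
    model <- match.arg(model)
    if (any(EDD <= 0)) stop("EDD must be > 0")
    if (any(ESD < 0) || any(ESD > EDD)) stop("need 0 <= ESD <= EDD")
    if (any(chamberLength <= 0)) stop("chamberLength must be > 0")
    structure(pi / 4 * (EDD^2 - ESD^2) * chamberLength, model = model)
}

#' Nucleolar-to-nuclear size ratio
#'
#' Ratio of nucleolar to nuclear size (areas or volumes — units must
#' match). Nucleolar size tracks ribosome biogenesis and hence biosynthetic
#' capacity. Ratios of at least 1 are implausible and warned about.
#'
#' @param nucleolar,nuclear sizes in the same units (> 0).
#' @return dimensionless ratio.
#' @export
nucleolarRatio <- function(nucleolar, nuclear) {
    if (any(nuclear <= 0) || any(nucleolar <= 0))
        stop("sizes must be > 0")
    if (any(nucleolar >= nuclear))
        warning("nucleolar size >= nuclear size; check units/segmentation")
    nucleolar / nuclear
}

#' Normalize a count or intensity to a volume
#'
#' E.g. fat-cell counts per pupal volume, or protein-synthesis (OPP)
#' intensity per cell volume.
#'
#' @param value count or intensity (>= 0).
#' @param volume normalizing volume (> 0).
#' @return \code{value / volume}.
#' @export
normalizePerVolume <- function(value, volume) {
    if (any(volume <= 0)) stop("volume must be > 0")
    if (any(value < 0)) stop("value must be >= 0")
    value / volume
}

#' qPCR fold changes relative to the female mean
#'
#' For each gene, Cq values are normalized to the mean female Cq
#' (\code{deltaCq = Cq - mean(female Cq)}) and converted to fold changes as
#' \code{2 ^ abs(deltaCq)}; each sample's folds are then divided by that
#' sample's mean fold across the reference genes. The absolute-value rule is
#' reproduced as printed — it deliberately folds down-regulation onto
#' up-regulation, so every fold is >= 1 before reference scaling; a signed
#' variant (\code{2 ^ -deltaCq}, low Cq = high expression = fold > 1) is
#' available with \code{signed = TRUE} and is not the printed rule.
#'
#' @param cq \code{data.frame} with columns \code{sample_id}, \code{sex}
#'   (\code{"female"}/\code{"male"}), \code{gene}, \code{Cq}.
#' @param referenceGenes genes whose mean fold normalizes each sample
#'   (default actin and beta-tubulin).
#' @param signed use the signed rule instead of the printed absolute rule.
#' @return \code{cq} with added columns \code{delta_Cq}, \code{fold}
#'   (pre-reference), \code{ref_fold}, \code{fold_norm}.
#' @examples
#' cq <- data.frame(sample_id = c("f1", "f2", "m1"),
#'                  sex = c("female", "female", "male"),
#'                  gene = "RpL3", Cq = c(20, 20, 19))
#' ref <- expand.grid(sample_id = c("f1", "f2", "m1"),
#'                    gene = c("actin", "beta-tubulin"))
#' ref$sex <- c("female", "female", "male")
#' ref$Cq <- 25
#' qpcrFoldChange(rbind(cq, ref))  # male RpL3 fold 2.0
#' @export
qpcrFoldChange <- function(cq, referenceGenes = c("actin", "beta-tubulin"),
                           signed = FALSE) {
    need <- c("sample_id", "sex", "gene", "Cq")
    miss <- setdiff(need, names(cq))
    if (length(miss)) stop("cq table lacks column(s): ",
                           paste(miss, collapse = ", "))
    missRef <- setdiff(referenceGenes, unique(cq$gene))
    if (length(missRef))
        stop("reference gene(s) missing from table: ",
             paste(missRef, collapse = ", "))
    out <- cq
    out$delta_Cq <- NA_real_
    for (g in unique(out$gene)) {
        i <- out$gene == g
        fem <- out$Cq[i & out$sex == "female"]
        if (!length(fem))
            stop("no female samples for gene '", g,
                 "' to define the baseline")
        out$delta_Cq[i] <- out$Cq[i] - mean(fem)
    }
    out$fold <- if (signed) 2^(-out$delta_Cq) else 2^abs(out$delta_Cq)
    refFold <- vapply(split(out, out$sample_id), function(d)
        mean(d$fold[d$gene %in% referenceGenes]), numeric(1))
    out$ref_fold <- refFold[out$sample_id]
    if (anyNA(out$ref_fold))
        stop("sample(s) without reference-gene measurements: ",
             paste(unique(out$sample_id[is.na(out$ref_fold)]), collapse = ", "))
    out$fold_norm <- out$fold / out$ref_fold
    out
}

#' Batch morphometry over a measurement table
#'
#' Adds derived columns to a measurement CSV/data.frame wherever the input
#' columns of a calculator are present: \code{volume} (from
#' \code{longitudinal_area} + \code{thickness}), \code{total_nuclei} (+
#' \code{analyzed_volume}, \code{counted_nuclei}), \code{density},
#' \code{FS} (from \code{EDD}, \code{ESD}), \code{SV} (+
#' \code{chamber_length}), \code{nucleolar_nuclear_ratio} (from
#' \code{nucleolar_size}, \code{nuclear_size}).
#'
#' @param measurements \code{data.frame} or path to a CSV with a header.
#' @param file optional output CSV path.
#' @return the augmented \code{data.frame}, invisibly if written.
#' @export
morphoTable <- function(measurements, file = NULL) {
    d <- if (is.character(measurements))
        utils::read.csv(measurements, stringsAsFactors = FALSE)
    else measurements
    has <- function(...) all(c(...) %in% names(d))
    if (has("longitudinal_area", "thickness"))
        d$volume <- muscleVolume(d$longitudinal_area, d$thickness)
    if (has("volume", "analyzed_volume", "counted_nuclei")) {
        d$total_nuclei <- extrapolateNuclei(d$volume, d$analyzed_volume,
                                            d$counted_nuclei)
        d$density <- nuclearDensity(d$total_nuclei, d$volume)
    }
    if (has("EDD", "ESD")) {
        d$FS <- fractionalShortening(d$EDD, d$ESD)
        if (has("chamber_length")) {
            d$SV <- as.numeric(strokeVolume(d$EDD, d$ESD, d$chamber_length))
            d$SV_model <- "cylindrical"
        }
    }
    if (has("nucleolar_size", "nuclear_size"))
        d$nucleolar_nuclear_ratio <- nucleolarRatio(d$nucleolar_size,
                                                    d$nuclear_size)
    if (!is.null(file)) {
        utils::write.csv(d, file, row.names = FALSE)
        return(invisible(d))
    }
    d
}
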