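#' Rule coverage counts on a labelled descriptor table
#'
#' A candidate rule \emph{covers} a compound when its expression value is
#' strictly positive. Coverage is tallied separately for carcinogens
#' (label 1, "positive") and non-carcinogens (label 0).
#'
#' @param rule an expression tree ([decode()]).
#' @param data data frame with descriptor columns and a binary label column.
#' @param label name of the label column (default \code{"label"}).
#' @return List with \code{p_cov}, \code{n_cov} (covered positives /
#'   negatives), \code{P_tot}, \code{N_tot} (class totals).
#' @export
coverage_counts <- function(rule, data, label = "label") {
  y <- data[[label]]
  if (is.null(y)) stop("label column '", label, "' not found")
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2)
    stop("both classes must be represented in the data")
  X <- data[setdiff(names(data), c(label, "id", "name"))]
  v <- evaluate(rule, X)
  fired <- v > 0
  list(p_cov = sum(fired & y == 1), n_cov = sum(fired & y == 0),
       P_tot = sum(y == 1), N_tot = sum(y == 0))
}

#' Rule significance (consistency gain over the base rate)
#'
#' \code{consig = (p/(p+n) - P/(P+N)) * P/(P+N)}: how far the precision of
#' the rule on the compounds it covers exceeds the positive base rate,
#' weighted by that base rate. A rule that fires on nothing scores 0 (the
#' limit of the base-rate comparison).
#'
#' @param f coverage counts from [coverage_counts()].
#' @return Numeric scalar.
#' @examples
#' consig(list(p_cov = 10, n_cov = 0, P_tot = 10, N_tot = 10))  # 0.25
#' @export
consig <- function(f) {
  covered <- f$p_cov + f$n_cov
  if (covered == 0) return(0)
  base <- f$P_tot / (f$P_tot + f$N_tot)
  (f$p_cov / covered - base) * base
}

#' Rule completeness (positive coverage fraction)
#'
#' \code{compl = p / P}: the fraction of all positives the rule covers.
#'
#' @inheritParams consig
#' @return Numeric in [0, 1].
#' @export
compl <- function(f) {
  if (f$P_tot < 1) stop("P_tot must be >= 1")
  f$p_cov / f$P_tot
}

#' Fitness of a classification rule
#'
#' Two modes. \code{"printed"} follows the published fitness verbatim:
#' 0 when \code{consig < 0}, otherwise \code{consig * log(compl - 1)} under
#' the protected log. Because \code{compl <= 1} always, the log argument is
#' never positive and the protected log returns 0, so this mode is
#' degenerate (identically 0); it is retained for fidelity and exposed for
#' inspection, never used to drive evolution. \code{"hits"} (the default
#' operational mode) counts correctly classified compounds of both classes
#' under the strictly-positive decision rule.
#'
#' @inheritParams coverage_counts
#' @param mode \code{"hits"} or \code{"printed"}.
#' @return Non-negative finite scalar.
#' @export
rule_fitness <- function(rule, data, mode = c("hits", "printed"),
                         label = "label") {
  mode <- match.arg(mode)
  f <- coverage_counts(rule, data, label)
  if (mode == "printed") {
    cs <- consig(f)
    if (cs < 0) return(0)
    arg <- compl(f) - 1
    lg <- if (arg > 0) log(arg) else 0
    return(max(cs * lg, 0))
  }
  # hits: covered positives + uncovered negatives
  f$p_cov + (f$N_tot - f$n_cov)
}

#' Fitness-proportionate (roulette-wheel) selection
#'
#' Samples one population index with probability proportional to fitness.
#' When every fitness is zero the draw is uniform.
#'
#' @param fitness numeric vector of non-negative fitness values.
#' @return Integer index of the selected member.
#' @export
roulette_select <- function(fitness) {
  if (length(fitness) == 0) stop("empty population")
  if (all(fitness <= 0)) return(sample.int(length(fitness), 1))
  sample.int(length(fitness), 1, prob = fitness)
}

# --- genetic operators ---------------------------------------------------
# All operators preserve validity: head positions only ever receive
# head-legal tokens, tail positions only terminals.

#' Point mutation
#'
#' Each position is independently resampled with probability \code{rate};
#' head positions draw from operators and terminals, tail positions from
#' terminals only.
#'
#' @param c a valid [chromosome()].
#' @param rate per-position mutation probability.
#' @return A valid chromosome.
#' @export
mutate <- function(c, rate) {
  if (rate <= 0) return(c)
  fs <- c$function_set
  s <- c$symbols
  h <- c$head_length
  hit <- stats::runif(length(s)) < rate
  head_pool <- c(names(fs$functions), fs$terminals)
  nh <- sum(hit[1:h])
  if (nh) s[1:h][hit[1:h]] <- sample(head_pool, nh, replace = TRUE)
  tail_idx <- (h + 1):length(s)
  nt <- sum(hit[tail_idx])
  if (nt) s[tail_idx][hit[tail_idx]] <- sample(fs$terminals, nt, replace = TRUE)
  chromosome(s, h, fs, validate = FALSE)
}

#' Transposition operators
#'
#' \code{"IS"} (insertion sequence): a random short segment (length 1-3) is
#' copied to a random non-root head position; the head shifts right and is
#' truncated at the head boundary. \code{"RIS"} (root IS): the segment must
#' start at an operator token in the head and is inserted at the head root.
#' \code{"gene"}: identity for single-gene chromosomes.
#'
#' @param c a valid [chromosome()].
#' @param mode \code{"IS"}, \code{"RIS"} or \code{"gene"}.
#' @return A valid chromosome.
#' @export
transpose <- function(c, mode = c("IS", "RIS", "gene")) {
  mode <- match.arg(mode)
  if (mode == "gene") return(c)
  fs <- c$function_set
  s <- c$symbols
  h <- c$head_length
  if (h < 2) return(c)
  seg_len <- sample(1:3, 1)
  if (mode == "IS") {
    start <- sample.int(length(s) - seg_len + 1, 1)
    seg <- s[start:(start + seg_len - 1)]
    # tail tokens are terminals, so any segment is head-legal
    pos <- sample(2:h, 1)
    new_head <- append(s[1:h], seg, after = pos - 1)[1:h]
  } else {
    fpos <- which(s[1:h] %in% names(fs$functions))
    if (length(fpos) == 0) return(c)
    start <- fpos[sample.int(length(fpos), 1)]
    seg <- s[start:min(start + seg_len - 1, length(s))]
    new_head <- c(seg, s[1:h])[1:h]
  }
  chromosome(c(new_head, s[(h + 1):length(s)]), h, fs, validate = FALSE)
}

#' Recombination operators
#'
#' Both parents must share head length and function set, so cut indices are
#' aligned and tail positions only ever exchange tail material.
#' \code{"one_point"}: suffixes after one random cut are swapped;
#' \code{"two_point"}: the segment between two cuts is swapped;
#' \code{"gene"}: whole-chromosome swap (single-gene degenerate case).
#'
#' @param a,b valid [chromosome()]s of identical shape.
#' @param mode \code{"one_point"}, \code{"two_point"} or \code{"gene"}.
#' @return List of two valid child chromosomes.
#' @export
recombine <- function(a, b, mode = c("one_point", "two_point", "gene")) {
  mode <- match.arg(mode)
  if (a$head_length != b$head_length ||
      length(a$symbols) != length(b$symbols))
    stop("parents must share head length and chromosome length")
  s1 <- a$symbols; s2 <- b$symbols
  L <- length(s1)
  if (mode == "gene") {
    return(list(b, a))
  } else if (mode == "one_point") {
    cut <- sample(0:(L - 1), 1)
    if (cut > 0) {
      idx <- (cut + 1):L
      tmp <- s1[idx]; s1[idx] <- s2[idx]; s2[idx] <- tmp
    } else {
      tmp <- s1; s1 <- s2; s2 <- tmp
    }
  } else {
    cuts <- sort(sample.int(L, 2))
    idx <- cuts[1]:cuts[2]
    tmp <- s1[idx]; s1[idx] <- s2[idx]; s2[idx] <- tmp
  }
  list(chromosome(s1, a$head_length, a$function_set, validate = FALSE),
       chromosome(s2, a$head_length, a$function_set, validate = FALSE))
}

#' Control parameters for the evolutionary loop
#'
#' Defaults follow canonical desk-scale GEP practice: population 100,
#' up to 500 generations, head length 7, point mutation 0.05 per position,
#' IS / RIS transposition 0.1 each, one- and two-point recombination 0.3
#' each, one elite carried unchanged.
#'
#' @param population population size.
#' @param generations maximum number of generations.
#' @param head_length chromosome head length.
#' @param mutation_rate per-position mutation probability.
#' @param is_rate,ris_rate,gene_rate per-individual transposition
#'   probabilities.
#' @param one_point_rate,two_point_rate,gene_recomb_rate per-pair
#'   recombination probabilities.
#' @param elitism number of elites copied unchanged (must be <
#'   \code{population}).
#' @param fitness fitness mode, \code{"hits"} or \code{"printed"}.
#' @param stop_when_perfect stop early once a rule classifies every
#'   training compound correctly (hits mode only).
#' @param seed optional integer seed fixing the whole evolution trace.
#' @return A list of class \code{"gep_control"}.
#' @export
gep_control <- function(population = 100, generations = 500, head_length = 7,
                        mutation_rate = 0.05, is_rate = 0.1, ris_rate = 0.1,
                        gene_rate = 0, one_point_rate = 0.3,
                        two_point_rate = 0.3, gene_recomb_rate = 0,
                        elitism = 1, fitness = c("hits", "printed"),
                        stop_when_perfect = TRUE, seed = NULL) {
  fitness <- match.arg(fitness)
  rates <- c(mutation_rate, is_rate, ris_rate, gene_rate,
             one_point_rate, two_point_rate, gene_recomb_rate)
  if (any(rates < 0 | rates > 1)) stop("operator rates must lie in [0, 1]")
  if (elitism >= population) stop("elitism must be smaller than population")
  structure(list(population = population, generations = generations,
                 head_length = head_length, mutation_rate = mutation_rate,
                 is_rate = is_rate, ris_rate = ris_rate, gene_rate = gene_rate,
                 one_point_rate = one_point_rate,
                 two_point_rate = two_point_rate,
                 gene_recomb_rate = gene_recomb_rate, elitism = elitism,
                 fitness = fitness, stop_when_perfect = stop_when_perfect,
                 seed = seed),
            class = "gep_control")
}

# fitness of one chromosome on a prepared (X, y) pair; hits mode inlined for
# speed inside the generational loop
.chrom_hits <- function(chrom, X, y) {
  v <- evaluate(decode(chrom), X)
  sum((v > 0) == (y == 1))
}

#' Run the GEP generational loop
#'
#' Initializes a random valid population, then per generation: evaluates
#' fitness, carries the elites, refills by roulette selection, and applies
#' mutation, IS/RIS transposition and one-/two-point recombination at the
#' configured rates. Returns the best individual ever seen together with the
#' per-generation fitness history. Fully reproducible given
#' \code{control$seed}.
#'
#' @param data labelled descriptor data frame (descriptor columns + binary
#'   label column; \code{id}/\code{name} columns are ignored).
#' @param control a [gep_control()].
#' @param function_set a [function_set()]; defaults to the extended
#'   arithmetic alphabet over the descriptor columns.
#' @param label label column name.
#' @return List with \code{best} (chromosome), \code{fitness} (best fitness),
#'   \code{history} (data frame: generation, best, mean) and
#'   \code{max_fitness} (the attainable ceiling in hits mode).
#' @export
gep_evolve <- function(data, control = gep_control(), function_set = NULL,
                       label = "label") {
  y <- data[[label]]
  if (is.null(y)) stop("label column '", label, "' not found")
  if (length(unique(y)) < 2) stop("both classes must be represented")
  X <- data[setdiff(names(data), c(label, "id", "name"))]
  X <- X[vapply(X, is.numeric, logical(1))]
  if (is.null(function_set)) function_set <- fset_extended(names(X))
  if (!is.null(control$seed)) set.seed(control$seed)
  fs <- function_set
  pop <- replicate(control$population,
                   random_chromosome(control$head_length, fs),
                   simplify = FALSE)
  score <- function(ch) {
    if (control$fitness == "hits") .chrom_hits(ch, X, y)
    else rule_fitness(decode(ch), data, mode = "printed", label = label)
  }
  fit <- vapply(pop, score, numeric(1))
  best_i <- which.max(fit)
  best <- pop[[best_i]]; best_fit <- fit[best_i]
  hist_best <- max(fit); hist_mean <- mean(fit)
  max_fit <- if (control$fitness == "hits") length(y) else Inf
  gen <- 0L
  while (gen < control$generations &&
         !(control$stop_when_perfect && best_fit >= max_fit)) {
    gen <- gen + 1L
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(control$elitism)]
    new_pop <- pop[elite_idx]
    while (length(new_pop) < control$population) {
      ch <- pop[[roulette_select(fit)]]
      ch <- mutate(ch, control$mutation_rate)
      if (stats::runif(1) < control$is_rate)  ch <- transpose(ch, "IS")
      if (stats::runif(1) < control$ris_rate) ch <- transpose(ch, "RIS")
      if (stats::runif(1) < control$gene_rate) ch <- transpose(ch, "gene")
      new_pop[[length(new_pop) + 1L]] <- ch
    }
    # pairwise recombination over the non-elite block
    ne <- (control$elitism + 1):control$population
    i <- 1
    while (i < length(ne)) {
      a <- ne[i]; b <- ne[i + 1]
      if (stats::runif(1) < control$one_point_rate) {
        ch2 <- recombine(new_pop[[a]], new_pop[[b]], "one_point")
        new_pop[[a]] <- ch2[[1]]; new_pop[[b]] <- ch2[[2]]
      }
      if (stats::runif(1) < control$two_point_rate) {
        ch2 <- recombine(new_pop[[a]], new_pop[[b]], "two_point")
        new_pop[[a]] <- ch2[[1]]; new_pop[[b]] <- ch2[[2]]
      }
      if (stats::runif(1) < control$gene_recomb_rate) {
        ch2 <- recombine(new_pop[[a]], new_pop[[b]], "gene")
        new_pop[[a]] <- ch2[[1]]; new_pop[[b]] <- ch2[[2]]
      }
      i <- i + 2
    }
    pop <- new_pop
    fit <- vapply(pop, score, numeric(1))
    gi <- which.max(fit)
    if (fit[gi] > best_fit) { best <- pop[[gi]]; best_fit <- fit[gi] }
    hist_best <- c(hist_best, max(fit)); hist_mean <- c(hist_mean, mean(fit))
  }
  list(best = best, fitness = best_fit,
       history = data.frame(generation = seq_along(hist_best) - 1L,
                            best = hist_best, mean = hist_mean),
       max_fitness = max_fit)
}
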