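#' @title Genetic-algorithm tuning of aligner parameters
#'
#' @description
#' Heavily mutated reads align poorly under default short-read aligner
#' settings, biasing damaged samples against their undamaged controls. The
#' tuner searches the aligner's parameter space with a small, seeded
#' genetic algorithm (tournament selection, uniform crossover,
#' domain-respecting per-gene mutation, elitism) against a pluggable
#' fitness in \[0, 1\] -- by default the fraction of simulated read pairs
#' aligning concordantly to the amplicon reference. The packaged default
#' genome renders the tuned Bowtie2 parameter set used for production
#' alignment.
#'
#' @name aligner_tuner
NULL

#' Define one tunable aligner parameter
#'
#' @param name Unique parameter name.
#' @param kind `"categorical"`, `"integer"`, `"real"`, `"integer2"` or
#'   `"real2"` (the `*2` kinds are linked two-component values rendered
#'   together, e.g. a match/mismatch penalty pair).
#' @param domain For categorical: the value set; for integer/real:
#'   `c(lo, hi)`; for the paired kinds: `list(c(lo, hi), c(lo, hi))`.
#' @param template Flag-rendering template; each `{}` is replaced by one
#'   formatted component. Categorical values render through the template
#'   too (default `"{}"`, i.e. the value itself).
#' @param fmt `sprintf` format for numeric components (default `"%d"` for
#'   integers, `"%g"` for reals).
#' @return A `tuner_param` list.
#' @export
tuner_param <- function(name, kind, domain, template = "{}", fmt = NULL) {
  kind <- match.arg(kind, c("categorical", "integer", "real",
                            "integer2", "real2"))
  fmt <- fmt %||% switch(kind, integer = "%d", integer2 = "%d", "%g")
  if (kind == "categorical" && !length(domain))
    stop("categorical domain must be non-empty")
  structure(list(name = name, kind = kind, domain = domain,
                 template = template, fmt = fmt),
            class = "tuner_param")
}

#' Assemble a parameter space
#'
#' @param ... `tuner_param` objects (names must be unique).
#' @return A `param_space` list.
#' @export
param_space <- function(...) {
  params <- list(...)
  nm <- vapply(params, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate parameter names")
  structure(setNames(params, nm), class = "param_space")
}

#' @export
print.param_space <- function(x, ...) {
  cat("param_space:", length(x), "parameters\n")
  for (p in x)
    cat(" ", p$name, "(", p$kind, ")\n")
  invisible(x)
}

# In-domain check for one gene value.
gene_in_domain <- function(p, v) {
  switch(p$kind,
    categorical = v %in% p$domain,
    integer = length(v) == 1L && v >= p$domain[1] && v <= p$domain[2] &&
      v == round(v),
    real = length(v) == 1L && v >= p$domain[1] && v <= p$domain[2],
    integer2 = ,
    real2 = length(v) == 2L &&
      v[1] >= p$domain[[1]][1] && v[1] <= p$domain[[1]][2] &&
      v[2] >= p$domain[[2]][1] && v[2] <= p$domain[[2]][2])
}

random_gene <- function(p) {
  switch(p$kind,
    categorical = sample(p$domain, 1L),
    integer = sample(seq.int(p$domain[1], p$domain[2]), 1L),
    real = runif(1L, p$domain[1], p$domain[2]),
    integer2 = c(sample(seq.int(p$domain[[1]][1], p$domain[[1]][2]), 1L),
                 sample(seq.int(p$domain[[2]][1], p$domain[[2]][2]), 1L)),
    real2 = c(runif(1L, p$domain[[1]][1], p$domain[[1]][2]),
              runif(1L, p$domain[[2]][1], p$domain[[2]][2])))
}

# Domain-respecting mutation: categorical/integer resample; reals perturb
# by a Gaussian with sd = 10% of the range, clipped to the domain.
mutate_gene <- function(p, v) {
  gauss <- function(x, d) min(max(x + rnorm(1L, 0, 0.1 * diff(d)), d[1]), d[2])
  switch(p$kind,
    categorical = if (length(p$domain) > 1L)
      sample(setdiff(p$domain, v), 1L) else v,
    integer = sample(seq.int(p$domain[1], p$domain[2]), 1L),
    real = gauss(v, p$domain),
    integer2 = {
      i <- sample(1:2, 1L)
      v[i] <- sample(seq.int(p$domain[[i]][1], p$domain[[i]][2]), 1L)
      v
    },
    real2 = {
      i <- sample(1:2, 1L)
      v[i] <- gauss(v[i], p$domain[[i]])
      v
    })
}

#' Random genome in a space
#'
#' @param space A `param_space`.
#' @return Named list, one in-domain value per parameter.
#' @export
random_genome <- function(space) lapply(space, random_gene)

#' Render a genome as an aligner argument string
#'
#' Formats each gene through its parameter's template and joins the
#' non-empty tokens with single spaces. With the packaged
#' [default_aligner_space()] and [default_aligner_genome()], this renders
#' the production Bowtie2 parameter set verbatim.
#'
#' @param genome Named list of gene values.
#' @param space The `param_space` the genome lives in.
#' @return A single argument string.
#' @export
emit_aligner_args <- function(genome, space) {
  if (!length(space)) return("")
  toks <- vapply(names(space), function(nm) {
    p <- space[[nm]]
    v <- genome[[nm]]
    if (is.null(v)) stop("genome is missing gene '", nm, "'")
    if (!gene_in_domain(p, v))
      stop("gene '", nm, "' value out of domain")
    out <- p$template
    comps <- if (p$kind == "categorical") as.character(v)
             else sprintf(p$fmt, v)
    for (cmp in comps) out <- sub("{}", cmp, out, fixed = TRUE)
    out
  }, "")
  paste(toks[nzchar(toks)], collapse = " ")
}

#' GA hyperparameters
#'
#' Defaults: population 24, 30 generations, tournament size 3, crossover
#' probability 0.7, per-gene mutation probability 0.1, 2 elites.
#'
#' @param population,generations,tournament,p_crossover,p_mutation,elites
#'   GA settings; `population >= elites + 2`, probabilities in \[0, 1\].
#' @param seed Required RNG seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population = 24L, generations = 30L, tournament = 3L,
                      p_crossover = 0.7, p_mutation = 0.1, elites = 2L,
                      seed) {
  if (population < elites + 2L) stop("population must be >= elites + 2")
  if (any(c(p_crossover, p_mutation) < 0 | c(p_crossover, p_mutation) > 1))
    stop("probabilities must lie in [0, 1]")
  if (missing(seed) || is.na(seed)) stop("ga_config requires a seed")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elites = as.integer(elites), seed = as.integer(seed)),
            class = "ga_config")
}

#' Optimise a fitness over a parameter space with a seeded GA
#'
#' Tournament selection, uniform crossover, per-gene domain-respecting
#' mutation and elitism; the elite copy guarantees the best-so-far fitness
#' is non-decreasing across generations, and a fixed seed makes the whole
#' trajectory reproducible.
#'
#' @param space A `param_space`.
#' @param fitness Function mapping a genome (named list) to a score in
#'   \[0, 1\]; must be deterministic given the genome.
#' @param config A [ga_config()].
#' @return `list(best_genome, best_fitness, history)`; `history` has one
#'   row per generation with `best`, `mean` and cumulative `best_so_far`
#'   fitness.
#' @export
ga_optimize <- function(space, fitness, config) {
  set.seed(config$seed)
  score <- function(g) {
    f <- fitness(g)
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
      stop("fitness contract error: score must be a single number in [0, 1]")
    f
  }
  pop <- replicate(config$population, random_genome(space), simplify = FALSE)
  fit <- vapply(pop, score, 0)
  hist <- data.frame(generation = integer(0), best = numeric(0),
                     mean = numeric(0), best_so_far = numeric(0))
  best_i <- which.max(fit)
  best <- list(genome = pop[[best_i]], fitness = fit[best_i])
  hist[1, ] <- c(0, max(fit), mean(fit), best$fitness)
  tourney <- function() {
    cand <- sample.int(config$population, config$tournament)
    cand[which.max(fit[cand])]
  }
  for (gen in seq_len(config$generations)) {
    ord <- order(fit, decreasing = TRUE)
    nxt <- pop[ord[seq_len(config$elites)]]
    while (length(nxt) < config$population) {
      a <- pop[[tourney()]]; b <- pop[[tourney()]]
      child <- if (runif(1L) < config$p_crossover)
        setNames(lapply(names(space), function(nm)
          if (runif(1L) < 0.5) a[[nm]] else b[[nm]]), names(space))
      else a
      for (nm in names(space))
        if (runif(1L) < config$p_mutation)
          child[[nm]] <- mutate_gene(space[[nm]], child[[nm]])
      nxt[[length(nxt) + 1L]] <- child
    }
    pop <- nxt
    fit <- vapply(pop, score, 0)
    gi <- which.max(fit)
    if (fit[gi] > best$fitness)
      best <- list(genome = pop[[gi]], fitness = fit[gi])
    hist[gen + 1L, ] <- c(gen, fit[gi], mean(fit), best$fitness)
  }
  list(best_genome = best$genome, best_fitness = best$fitness,
       history = hist)
}

#' The production aligner parameter space
#'
#' The Bowtie2 flags exposed to the tuner: pairing mode, insert limit,
#' pair-rescue switches, quality handling, seeding effort (`-D`, `-R`,
#' `-L`, `-N`), penalty settings (`--np`, `--dpad`, `--gbar`, the linked
#' `--mp` pair, `--rdg`/`--rfg` gap penalties) and the linear `--score-min`
#' intercept/slope pair.
#'
#' @return A `param_space`.
#' @export
default_aligner_space <- function() {
  param_space(
    tuner_param("pairing", "categorical", c("--fr", "--rf", "--ff")),
    tuner_param("maxins", "integer", c(200L, 800L), "--maxins {}"),
    tuner_param("discordant", "categorical", c("--no-discordant", "")),
    tuner_param("mixed", "categorical", c("--no-mixed", "")),
    tuner_param("quals", "categorical", c("--ignore-quals", "")),
    tuner_param("upfront", "categorical", c("--no-1mm-upfront", "")),
    tuner_param("seed_extends", "integer", c(5L, 100L), "-D {}"),
    tuner_param("reseed", "integer", c(1L, 50L), "-R {}"),
    tuner_param("seed_len", "integer", c(18L, 32L), "-L {}"),
    tuner_param("seed_mm", "integer", c(0L, 1L), "-N {}"),
    tuner_param("np", "integer", c(0L, 2L), "--np {}"),
    tuner_param("dpad", "integer", c(10L, 150L), "--dpad {}"),
    tuner_param("gbar", "integer", c(1L, 8L), "--gbar {}"),
    tuner_param("mp", "real2", list(c(1, 8), c(0.1, 2)), "--mp {},{}"),
    tuner_param("rdg", "integer2", list(c(0L, 10L), c(0L, 10L)),
                "--rdg {},{}"),
    tuner_param("rfg", "integer2", list(c(0L, 10L), c(0L, 10L)),
                "--rfg {},{}"),
    tuner_param("score_min", "real2", list(c(-2, 0), c(-2, 0)),
                "--score-min L,{},{}", fmt = "%.1f"))
}

#' The tuned production genome
#'
#' Renders (via [emit_aligner_args()]) to the parameter string used for
#' production alignment of heavily mutated amplicon reads:
#' `--fr --maxins 400 --no-discordant --no-mixed --ignore-quals
#' --no-1mm-upfront -D 100 -R 50 -L 28 -N 1 --np 0 --dpad 49 --gbar 2
#' --mp 3.2,0.35 --rdg 1,1 --rfg 5,2 --score-min L,-1.0,-0.5`.
#'
#' @return Named list of gene values for [default_aligner_space()].
#' @export
default_aligner_genome <- function() {
  list(pairing = "--fr", maxins = 400L, discordant = "--no-discordant",
       mixed = "--no-mixed", quals = "--ignore-quals",
       upfront = "--no-1mm-upfront", seed_extends = 100L, reseed = 50L,
       seed_len = 28L, seed_mm = 1L, np = 0L, dpad = 49L, gbar = 2L,
       mp = c(3.2, 0.35), rdg = c(1L, 1L), rfg = c(5L, 2L),
       score_min = c(-1.0, -0.5))
}

#' Concordant-alignment-rate fitness against an external aligner
#'
#' Renders the genome into Bowtie2 arguments, builds an index for the
#' amplicon reference, aligns the read pair and parses the fraction of
#' pairs aligned concordantly (exactly once or more) from the aligner's
#' summary. This fitness needs the `bowtie2` and `bowtie2-build`
#' executables on the path; everything else in the tuner is testable with
#' synthetic fitness functions and does not require them.
#'
#' @param r1_path,r2_path Paired FASTQ files.
#' @param reference_fasta Amplicon reference (see
#'   [write_reference_fasta()]).
#' @param genome,space Genome to score and its space.
#' @param aligner,indexer Executable names.
#' @param work_dir Scratch directory for index and logs.
#' @return Concordant-pair fraction in \[0, 1\]; 0 (with a warning) for
#'   empty input.
#' @export
alignment_efficiency_fitness <- function(r1_path, r2_path, reference_fasta,
                                         genome, space,
                                         aligner = "bowtie2",
                                         indexer = "bowtie2-build",
                                         work_dir = tempfile("tune_")) {
  for (exe in c(aligner, indexer))
    if (Sys.which(exe) == "")
      stop("external aligner '", exe, "' not found on PATH; install it or ",
           "use a synthetic fitness function instead")
  n_pairs <- fastq_n_records(r1_path)
  if (n_pairs == 0L) {
    warning("empty FASTQ input; fitness defined as 0")
    return(0)
  }
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- file.path(work_dir, "ref_index")
  st <- system2(indexer, c(shQuote(reference_fasta), shQuote(idx)),
                stdout = file.path(work_dir, "index.log"),
                stderr = file.path(work_dir, "index.log"))
  if (st != 0L) stop("indexer failed (exit ", st, "); see ",
                     file.path(work_dir, "index.log"))
  log <- file.path(work_dir, "align.log")
  st <- system2(aligner,
                c(emit_aligner_args(genome, space), "-x", shQuote(idx),
                  "-1", shQuote(r1_path), "-2", shQuote(r2_path),
                  "-S", shQuote(file.path(work_dir, "out.sam"))),
                stdout = log, stderr = log)
  if (st != 0L) stop("aligner failed (exit ", st, "); log: ",
                     paste(readLines(log), collapse = "\n"))
  txt <- readLines(log)
  sel <- txt[grepl("aligned concordantly (exactly 1 time|>1 times)", txt)]
  hits <- regmatches(sel, regexpr("^\\s*\\d+", sel))
  if (!length(hits)) stop("could not parse concordant counts from the ",
                          "aligner summary; log: ", log)
  sum(as.numeric(trimws(hits))) / n_pairs
}

fastq_n_records <- function(path) {
  con <- open_fastq(path)
  on.exit(close(con))
  n <- 0L
  repeat {
    chunk <- readLines(con, 40000L)
    if (!length(chunk)) break
    n <- n + length(chunk)
  }
  n %/% 4L
}
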