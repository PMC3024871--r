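# pedhla

Pedigree-based HLA allele imputation via weighted haplotype similarity
graphs.

## What it does, and for whom

Classical HLA genes (HLA-A, -B, -C, -DRB1, -DQA1, -DQB1) are so
polymorphic that direct typing by serology or PCR is a bottleneck for
large studies, while SNP genotypes around the MHC are cheap and
abundant. Because a chromosome carrying a given HLA allele tends to
carry a distinctive SNP *background haplotype*, the HLA types of
untyped individuals can be inferred computationally from (i) SNP
genotypes of a population of pedigrees in a window around the gene and
(ii) the known, unphased HLA types of a reference subset. `pedhla` is
for statistical geneticists who have exactly those two inputs.

The method treats phasing and type assignment as one joint
optimization:

1. **Pedigree phasing space.** Under Mendelian and zero-recombinant
   constraints, all haplotype configurations of a pedigree form an
   affine subspace over GF(2) with `f` free binary variables and
   exactly `2^f` solutions (a greedy segmented fallback absorbs
   obligate crossovers).
2. **Similarity.** Two haplotypes are compared through *maximum regions
   of nearly identical matching*: a region `[p, q]` with matching
   endpoints and no run of more than `T_mis` consecutive mismatches;
   `Similarity = N*/n`, the maximal number of matching loci in such a
   region over the window length. Identical fully observed haplotypes
   score exactly 1.
3. **Constrained graph labeling.** A graph with two vertices per
   individual, complete similarity edges `w_pq`, and one constraint
   edge per typed individual carrying its unordered allele pair
   `{α, β}` is labeled feasibly so that the within-label weight
   `Con = Σ_{l(p)=l(q)} w_pq` is large (deterministic heuristic, exact
   exponential labeler as test oracle).
4. **Configuration search.** Pedigrees are committed in ascending `f`:
   forced pedigrees seed the graph, small spaces are enumerated
   exhaustively (`f ≤ T_c = 10`), large ones are searched by a genetic
   algorithm (population 400, 50 generations, crossover 0.8, mutation
   0.2) whose chromosomes are the free-variable vectors themselves.
5. **Calling.** An untyped individual is typed from the maximum-weight
   labeled neighbors of its two vertices; weak support (below
   `T_s = 0.65`) yields a no-call. Evaluation counts chromosomes:
   coverage `= N_called/N_analyzed`, accuracy `= N_correct/N_called`.

A pedigree population simulator with allele-specific backgrounds,
Mendelian transmission and optional recombination/missingness/error,
plus leave-one-out and leave-one-pedigree-out harnesses, make the whole
chain testable without external data.

## Worked example

The packaged fixture has three homozygous-typed reference singletons
(one per allele), two heterozygous-typed individuals, and one untyped
individual whose true pair is `{0101, 2401}`:

```r
library(pedhla)
fx <- makeWorkedFixture()
fx$pop
#> HlaPopulation: 6 individuals in 6 pedigrees, 12 markers, 5 HLA-typed
res <- runHlaInference(fx$pop, RunConfig())
callTable(res)
#>   id allele1 allele2 status w1 w2
#> 1 R1    0201    0201  known NA NA
#> 2 R2    0101    0101  known NA NA
#> 3 R3    2401    2401  known NA NA
#> 4 I1    0201    0101  known NA NA
#> 5 I2    0201    2401  known NA NA
#> 6 I3    0101    2401 called  1  1
```

Typed individuals pass through as `known`. `I3` is `called` with both
alleles correct; the support weights `w1 = w2 = 1` say that each of its
two phased haplotypes is an exact copy of a labeled reference
background. The run log shows how each pedigree was committed
(`unique` for forced phases, `enum`/`ga` otherwise) and the growing
objective:

```r
runLog(res)
#>   family f method con
#> 1     P1 0 unique   3
#> 2     P2 0 unique   3
#> 3     P3 0 unique   3
#> 4     P4 5   enum   7
#> 5     P5 5   enum  12
#> 6     P6 5   enum  18
```

At scale, the same call on a simulated 20-family population under
leave-one-out masking recovers every held-out type
(`leaveOneOut(simulatePopulation(SimConfig(seed = 20))$pop, RunConfig())`
reports coverage 100%, accuracy 100%; with 1% genotype missingness the
accuracy stays above 95%).

A thin command-line front end over the same functions is installed at
`inst/cli/pedhla.R` with subcommands `simulate`, `infer`, `eval-loo`
and `eval-lopo`:

```sh
Rscript inst/cli/pedhla.R simulate --out-prefix sim --seed 1
Rscript inst/cli/pedhla.R infer --ped sim.ped --map sim.map --hla sim.hla \
    --gene-center 31500000 --window-kb 200 --resolution 4 --seed 1
```

File formats are PED-style genotypes (alleles 1/2, 0 missing), a
3-column marker map, and a TSV HLA table with `-` for unknown; see
`?readPopulation`.

## Documentation

The methods vignette (`vignettes/pedigree-hla-imputation.Rmd`) explains
the model, every tunable parameter with its default, the numerical
choices and reconstructions, what the simulator does and does not
emulate, and known limitations.
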