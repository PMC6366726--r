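"""Coalescent simulation worker.

Reads a JSON job description, runs msprime, and writes plain-text results:
one newick string per line for genealogy jobs, or haplotype blocks for
sequence-window jobs.  Invoked by the R simulation layer; not a user-facing
script.

Usage: python coalsim.py JOB.json OUT.txt
"""
import json
import sys

import msprime


def build_demography(spec, migration_rates=None):
    """Build an msprime Demography from the generic model description.

    migration_rates: optional list of [donor, recipient, m] overriding the
    per-lineage forward migration rates for this locus.  Forward migration
    donor -> recipient at per-lineage fraction m corresponds, backwards in
    time, to lineages in the recipient jumping to the donor.
    """
    dem = msprime.Demography()
    for pop in spec["populations"]:
        dem.add_population(name=pop["name"], initial_size=pop["size"])
    for sp in spec.get("splits", []):
        dem.add_population_split(
            time=sp["time"], derived=list(sp["derived"]),
            ancestral=sp["ancestral"])
    for sc in spec.get("size_changes", []):
        dem.add_population_parameters_change(
            time=sc["time"], population=sc["population"],
            initial_size=sc["size"])
    for pulse in spec.get("pulses", []):
        if pulse["fraction"] > 0:
            dem.add_mass_migration(
                time=pulse["time"], source=pulse["recipient"],
                dest=pulse["donor"], proportion=pulse["fraction"])
    rates = migration_rates
    if rates is None:
        rates = [[e["donor"], e["recipient"], e.get("rate", 0.0)]
                 for e in spec.get("migration", [])]
    for donor, recipient, m in rates:
        if m > 0:
            dem.set_migration_rate(source=recipient, dest=donor, rate=m)
    dem.sort_events()
    return dem


def tip_labels(ts):
    labels = {}
    for pop in ts.populations():
        name = pop.metadata.get("name", f"pop{pop.id}")
        for j, u in enumerate(ts.samples(population=pop.id)):
            labels[u] = f"{name}_{j + 1}"
    return labels


def run_genealogies(job, out):
    spec = job["demography"]
    # haploid tips on the diploid-scaled model (pair coalescence 1/(2N))
    samples = [msprime.SampleSet(int(v), population=k, ploidy=1)
               for k, v in job["samples"].items()]
    seeds = job["seeds"]
    per_locus = job.get("migration_rates")  # list (loci) of [d, r, m] lists
    if per_locus is None:
        dem = build_demography(spec)
        reps = msprime.sim_ancestry(
            samples=samples, ploidy=2, demography=dem,
            random_seed=seeds[0], num_replicates=len(seeds))
        for ts in reps:
            tree = ts.first()
            out.write(tree.as_newick(node_labels=tip_labels(ts)) + "\n")
    else:
        for i, rates in enumerate(per_locus):
            dem = build_demography(spec, migration_rates=rates)
            ts = msprime.sim_ancestry(
                samples=samples, ploidy=2, demography=dem,
                random_seed=seeds[i])
            tree = ts.first()
            out.write(tree.as_newick(node_labels=tip_labels(ts)) + "\n")


def run_windows(job, out):
    spec = job["demography"]
    samples = {k: int(v) for k, v in job["samples"].items()}
    window_bp = int(job["window_bp"])
    mu = float(job["mu"])
    recomb = float(job["recomb_per_bp"])
    seeds = job["seeds"]
    fractions = job.get("pulse_fractions")
    sample_names = None
    for i, seed in enumerate(seeds):
        spec_i = dict(spec)
        if fractions is not None:
            pulses = []
            for p in spec.get("pulses", []):
                q = dict(p)
                q["fraction"] = fractions[i]
                pulses.append(q)
            spec_i["pulses"] = pulses
        dem = build_demography(spec_i)
        ts = msprime.sim_ancestry(
            samples=samples, ploidy=2, demography=dem,
            sequence_length=window_bp, recombination_rate=recomb,
            random_seed=seed)
        mts = msprime.sim_mutations(
            ts, rate=mu, random_seed=seed + 1,
            model=msprime.BinaryMutationModel(), discrete_genome=False)
        if sample_names is None:
            # two haplotypes per diploid individual, grouped by population
            names = []
            for pop in mts.populations():
                pname = pop.metadata.get("name", f"pop{pop.id}")
                for j, u in enumerate(mts.samples(population=pop.id)):
                    names.append(f"{pname}|{pname}_{j // 2 + 1}")
            out.write("#samples " + " ".join(names) + "\n")
            sample_names = names
        positions = []
        haps = []
        last = 0
        for var in mts.variants():
            pos = int(var.site.position) + 1
            if pos <= last:           # collapse float positions landing on
                continue              # the same bp after truncation
            if len(var.alleles) != 2:
                continue
            last = pos
            positions.append(pos)
            haps.append(var.genotypes)
        out.write(f"#window {i + 1} {window_bp} {len(positions)}\n")
        out.write(" ".join(str(p) for p in positions) + "\n")
        n_hap = mts.num_samples
        for h in range(n_hap):
            out.write("".join(str(g[h]) for g in haps) + "\n")


def main():
    job_path, out_path = sys.argv[1], sys.argv[2]
    with open(job_path) as fh:
        job = json.load(fh)
    with open(out_path, "w") as out:
        if job["kind"] == "genealogies":
            run_genealogies(job, out)
        elif job["kind"] == "windows":
            run_windows(job, out)
        else:
            raise ValueError(f"unknown job kind: {job['kind']}")


if __name__ == "__main__":
    main()
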