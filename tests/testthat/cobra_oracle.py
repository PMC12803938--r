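"""Independent reference oracle for the test suite.

Reads a model in the package JSON dialect plus a task description, runs the
reference constraint-based implementation (COBRApy with GLPK), and writes
the result as JSON. Used only by the tests to cross-check the R
implementation on tiny fixtures.

Usage: python cobra_oracle.py <model.json> <task.json> <out.json>
"""
import json
import sys

import cobra
from cobra.flux_analysis import flux_variability_analysis, pfba

cobra.Configuration().solver = "glpk"


def load_model(path):
    with open(path) as fh:
        doc = json.load(fh)
    model = cobra.Model("m")
    mets = {m["id"]: cobra.Metabolite(m["id"], compartment=m["compartment"])
            for m in doc["metabolites"]}
    for r in doc["reactions"]:
        rxn = cobra.Reaction(r["id"])
        rxn.lower_bound = r["lb"]
        rxn.upper_bound = r["ub"]
        model.add_reactions([rxn])
        rxn.add_metabolites({mets[k]: v for k, v in r["stoichiometry"].items()})
    model.objective = {model.reactions.get_by_id(k): v
                       for k, v in doc["objective"].items()}
    return model


def main():
    model_path, task_path, out_path = sys.argv[1:4]
    with open(task_path) as fh:
        task = json.load(fh)
    model = load_model(model_path)
    kind = task["task"]
    out = {}
    if kind == "fba":
        sol = model.optimize()
        out = {"objective": sol.objective_value}
    elif kind == "pfba":
        sol = pfba(model, fraction_of_optimum=task.get("fraction_of_optimum", 1.0))
        out = {"total_flux": float(sum(abs(v) for v in sol.fluxes)),
               "fluxes": {k: float(v) for k, v in sol.fluxes.items()}}
    elif kind == "fva":
        res = flux_variability_analysis(
            model,
            fraction_of_optimum=task.get("fraction_of_optimum", 1.0),
            loopless="cycleFreeFlux" if task.get("loopless") else None,
            pfba_factor=task.get("pfba_factor"))
        out = {"min": {k: float(v) for k, v in res["minimum"].items()},
               "max": {k: float(v) for k, v in res["maximum"].items()}}
    else:
        raise SystemExit(f"unknown task: {kind}")
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
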