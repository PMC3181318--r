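[
  {
    "name": "A-DAG1",
    "scenario": "replacement",
    "edges": [["RES", "BCC"], ["BCC", "SCC"], ["SCC", "PS"], ["PS", "BA"], ["BA", "BCM"]]
  },
  {
    "name": "A-DAG2",
    "scenario": "replacement",
    "edges": [["RES", "BCC"], ["RES", "SCC"], ["BCC", "SCC"], ["SCC", "PS"], ["PS", "BA"], ["BA", "BCM"]]
  },
  {
    "name": "A-DAG3",
    "scenario": "replacement",
    "edges": [["RES", "BCC"], ["BCC", "SCC"], ["SCC", "PS"], ["PS", "BA"], ["PS", "BCM"], ["BA", "BCM"]]
  },
  {
    "name": "A-DAG4",
    "scenario": "replacement",
    "edges": [["RES", "BCC"], ["BCC", "BA"], ["BCC", "SCC"], ["BA", "PS"], ["SCC", "PS"], ["PS", "BCM"], ["BA", "BCM"]]
  },
  {
    "name": "B-DAG1",
    "scenario": "adjustment",
    "edges": [["RES", "SCC"], ["SCC", "PS"], ["PS", "BCC"], ["PS", "BA"], ["BA", "BCM"]]
  },
  {
    "name": "B-DAG2",
    "scenario": "adjustment",
    "edges": [["RES", "SCC"], ["SCC", "PS"], ["PS", "BCC"], ["PS", "BA"], ["BA", "BCM"], ["BCC", "BCM"]]
  },
  {
    "name": "B-DAG3",
    "scenario": "adjustment",
    "edges": [["RES", "SCC"], ["SCC", "BCC"], ["SCC", "PS"], ["PS", "BA"], ["BA", "BCM"]]
  },
  {
    "name": "B-DAG4",
    "scenario": "adjustment",
    "edges": [["RES", "SCC"], ["SCC", "PS"], ["PS", "BA"], ["PS", "BCM"], ["BA", "BCM"], ["BCC", "PS"], ["BCC", "BCM"]]
  },
  {
    "name": "B-DAG5",
    "scenario": "adjustment",
    "edges": [["RES", "SCC"], ["SCC", "PS"], ["PS", "BA"], ["BA", "BCM"], ["BCC", "PS"], ["BCC", "BCM"]]
  }
]
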