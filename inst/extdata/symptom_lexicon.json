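[
  {"canonical": "chest pain",
   "synonyms": ["chest pain", "chest discomfort", "chest tightness", "chest heaviness", "angina", "retrosternal pain"]},
  {"canonical": "shortness of breath",
   "synonyms": ["shortness of breath", "sob", "dyspnea", "dyspnoea", "breathlessness", "difficulty breathing"]},
  {"canonical": "nausea or vomiting",
   "synonyms": ["nausea or vomiting", "nausea", "vomiting", "vomitting", "emesis"]},
  {"canonical": "sweating or diaphoresis",
   "synonyms": ["sweating or diaphoresis", "sweating", "diaphoresis", "perspiration", "profuse sweating"]},
  {"canonical": "abdominal pain",
   "synonyms": ["abdominal pain", "abdominal discomfort", "epigastric pain", "stomach pain"]},
  {"canonical": "arm pain",
   "synonyms": ["arm pain", "left arm pain", "arm heaviness"]},
  {"canonical": "ghabrahat",
   "synonyms": ["ghabrahat", "ghabrat", "ghabrahut"]},
  {"canonical": "weakness",
   "synonyms": ["weakness", "generalized weakness", "fatigue", "lethargy"]},
  {"canonical": "shoulder pain",
   "synonyms": ["shoulder pain", "shoulder discomfort"]},
  {"canonical": "palpitations",
   "synonyms": ["palpitations", "palpitation", "racing heart"]},
  {"canonical": "back pain",
   "synonyms": ["back pain", "backache"]},
  {"canonical": "altered mental status",
   "synonyms": ["altered mental status", "altered sensorium", "confusion", "drowsiness"]},
  {"canonical": "dizziness",
   "synonyms": ["dizziness", "giddiness", "vertigo", "lightheadedness"]},
  {"canonical": "jaw pain",
   "synonyms": ["jaw pain", "jaw discomfort"]},
  {"canonical": "orthopnea",
   "synonyms": ["orthopnea", "orthopnoea"]},
  {"canonical": "neck pain",
   "synonyms": ["neck pain", "neck stiffness"]},
  {"canonical": "throat pain",
   "synonyms": ["throat pain", "sore throat"]},
  {"canonical": "swelling",
   "synonyms": ["swelling", "edema", "oedema", "pedal edema"]}
]
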