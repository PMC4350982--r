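# Bundled name pools for the synthetic-IDAT generator.  Static lists so
# no download is ever needed; deliberately include umlaut and ß entries
# to exercise the transliteration path end to end.

FIRST_NAME_POOL <- c(
  "Alexander", "Andreas", "Anna", "Anneliese", "Antje", "Astrid", "Axel",
  "Barbara", "Beate", "Benjamin", "Bernd", "Bettina", "Birgit", "Björn",
  "Brigitte", "Carina", "Carsten", "Christa", "Christian", "Christina",
  "Claudia", "Cornelia", "Dagmar", "Daniel", "Daniela", "David", "Dennis",
  "Dieter", "Dirk", "Dominik", "Doris", "Edith", "Elena", "Elias",
  "Elisabeth", "Elke", "Emil", "Emma", "Erich", "Erika", "Ernst", "Eva",
  "Fabian", "Felix", "Florian", "Frank", "Franziska", "Friedrich", "Gabriele",
  "Georg", "Gerhard", "Gertrud", "Gisela", "Greta", "Günter", "Günther",
  "Hannah", "Hannelore", "Hans", "Heike", "Heinrich", "Heinz", "Helga",
  "Helmut", "Henning", "Herbert", "Hermann", "Hildegard", "Horst", "Ilse",
  "Ines", "Inge", "Ingrid", "Irene", "Iris", "Ivan", "Jan", "Jana", "Jens",
  "Joachim", "Johanna", "Johannes", "Jonas", "Josef", "Julia", "Julian",
  "Jürgen", "Jutta", "Kai", "Karin", "Karl", "Katharina", "Kerstin", "Klaus",
  "Kurt", "Laura", "Lea", "Lena", "Leon", "Lieselotte", "Linda", "Lisa",
  "Lothar", "Luca", "Ludwig", "Luise", "Lukas", "Manfred", "Manuela",
  "Marcel", "Marco", "Margarete", "Maria", "Marianne", "Mario", "Marion",
  "Markus", "Martin", "Martina", "Mathias", "Matthias", "Max", "Maximilian",
  "Melanie", "Michael", "Michaela", "Mia", "Monika", "Moritz", "Nadine",
  "Nicole", "Niklas", "Nina", "Noah", "Norbert", "Olaf", "Oliver", "Otto",
  "Paul", "Paula", "Peter", "Petra", "Philipp", "Rainer", "Ralf", "Rebecca",
  "Regina", "Renate", "René", "Richard", "Rita", "Robert", "Rolf", "Rosa",
  "Rudolf", "Ruth", "Sabine", "Sandra", "Sarah", "Sebastian", "Silke",
  "Simon", "Simone", "Sofia", "Sonja", "Stefan", "Stefanie", "Susanne",
  "Sven", "Tanja", "Theodor", "Thomas", "Thorsten", "Tim", "Tobias",
  "Torsten", "Ulrich", "Ulrike", "Ursula", "Uwe", "Vanessa", "Vera",
  "Verena", "Viktor", "Volker", "Walter", "Werner", "Wilhelm", "Wolfgang",
  "Yvonne", "Sören", "Jörg", "Jörn", "Käthe", "Löis", "Müriel"
)

LAST_NAME_POOL <- c(
  "Ackermann", "Albrecht", "Arnold", "Bachmann", "Barth", "Bauer", "Baumann",
  "Beck", "Becker", "Berger", "Bergmann", "Böhm", "Böttcher", "Brandt",
  "Braun", "Brunner", "Busch", "Dietrich", "Döring", "Ebert", "Eckert",
  "Engel", "Ernst", "Fellegi", "Fischer", "Frank", "Franke", "Friedrich",
  "Fuchs", "Gärtner", "Geiger", "Gerlach", "Graf", "Groß", "Günther",
  "Haas", "Hahn", "Hartmann", "Heinrich", "Herrmann", "Herzog", "Hess",
  "Heß", "Hoffmann", "Hofmann", "Horn", "Huber", "Jäger", "Jahn", "Jung",
  "Kaiser", "Kaufmann", "Keller", "Kern", "Klein", "Koch", "Köhler",
  "König", "Kraft", "Kramer", "Kraus", "Krause", "Krebs", "Krüger", "Kuhn",
  "Kunz", "Lang", "Lange", "Lehmann", "Lenz", "Lindner", "Lorenz", "Ludwig",
  "Lutz", "Maier", "Marx", "Mayer", "Meier", "Meyer", "Möller", "Müller",
  "Naumann", "Neumann", "Nowak", "Otto", "Peters", "Pfeiffer", "Pohl",
  "Reinhardt", "Richter", "Riedel", "Ritter", "Roth", "Sauer", "Schäfer",
  "Scharf", "Schenk", "Schilling", "Schlegel", "Schmid", "Schmidt",
  "Schmitt", "Schmitz", "Schneider", "Scholz", "Schreiber", "Schröder",
  "Schubert", "Schulte", "Schulz", "Schulze", "Schumacher", "Schuster",
  "Schwarz", "Schweizer", "Seidel", "Seifert", "Simon", "Sommer", "Stark",
  "Stein", "Steiner", "Straßburger", "Thiel", "Thomas", "Ullrich", "Vogel",
  "Vogt", "Voigt", "Völler", "Wagner", "Walter", "Weber", "Weiß", "Wendt",
  "Werner", "Westermann", "Wilhelm", "Winkler", "Winter", "Wolf", "Wolff",
  "Zimmermann", "Zöllner"
)
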