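# Bundled multi-locale name pools for the synthetic identity generator.
# Frequencies follow a Zipf-like decay so that common surnames form large
# linkage blocks and rare ones a long tail, as in real enrolment data.
# Sampling from bundled lists (rather than an external faker) keeps test
# fixtures hermetic and bit-reproducible.

FIRST_NAMES_F <- c(
  "Anna", "Maria", "Elena", "Sofia", "Laura", "Julia", "Emma", "Clara",
  "Alice", "Sara", "Lucia", "Martina", "Chiara", "Giulia", "Francesca",
  "Isabella", "Camille", "Charlotte", "Louise", "Amélie", "Inès",
  "Zoé", "Léa", "Margaux", "María", "Carmen", "Lucía",
  "Paula", "Marta", "Cristina", "Beatriz", "Inés", "Hanna", "Lena",
  "Mia", "Frieda", "Greta", "Katharina", "Johanna", "Helga", "Ursula",
  "Renate", "Ingrid", "Astrid", "Sigrid", "Birgit", "Magdalena",
  "Agnieszka", "Katarzyna", "Małgorzata", "Zuzanna", "Alicja",
  "Jadwiga", "Petra", "Jana", "Eva", "Zuzana", "Klára", "Tereza",
  "Veronika", "Adéla", "Ana", "Ivana", "Jelena", "Milica", "Dragana",
  "Svetlana", "Olga", "Irina", "Natalia", "Tatiana", "Ekaterina", "Fatima",
  "Amina", "Leila", "Yasmin", "Nadia", "Samira", "Zeynep", "Elif", "Ayşe",
  "Mariam", "Grace", "Ruth", "Esther", "Joy", "Blessing", "Amara", "Ngozi",
  "Adaeze", "Chioma", "Mercy", "Agnes", "Beatrice", "Florence", "Margaret",
  "Dorothy", "Eleanor", "Harriet", "Rosa", "Teresa", "Antonia", "Valentina",
  "Gabriela", "Fernanda", "Juliana", "Camila", "Renata", "Bianca",
  "Priya", "Ananya", "Divya", "Kavita", "Sunita", "Mei", "Ling", "Xiu",
  "Hui", "Yuki", "Sakura", "Hana", "Minji", "Soo-Jin"
)

FIRST_NAMES_M <- c(
  "Jan", "Peter", "Thomas", "Martin", "Michael", "Andreas", "Stefan",
  "Christian", "Daniel", "Markus", "Wolfgang", "Jürgen", "Klaus",
  "Dieter", "Helmut", "Lukas", "Felix", "Jonas", "Paul", "Leon", "Max",
  "Moritz", "Giovanni", "Marco", "Luca", "Alessandro", "Francesco",
  "Matteo", "Andrea", "Giuseppe", "Antonio", "Lorenzo", "Pierre", "Jean",
  "Louis", "Hugo", "Théo", "Antoine", "François", "René",
  "Olivier", "José", "Juan", "Carlos", "Miguel", "Javier", "Pablo",
  "Diego", "Andrés", "Rafael", "João", "Pedro", "Tiago", "Nuno",
  "Piotr", "Krzysztof", "Andrzej", "Tomasz", "Paweł", "Marek",
  "Łukasz", "Wojciech", "Jakub", "Jiří", "Pavel", "Petr",
  "Milan", "Ondřej", "Václav", "Ivan", "Nikola", "Marko",
  "Stefan", "Dragan", "Goran", "Aleksandar", "Sergei", "Dmitri", "Mikhail",
  "Alexei", "Omar", "Ahmed", "Youssef", "Karim", "Hassan", "Ali", "Mehmet",
  "Mustafa", "Emre", "Can", "David", "Samuel", "Joseph", "Daniel", "Emmanuel",
  "Chukwu", "Obi", "Kwame", "Kofi", "Sipho", "Thabo", "James", "William",
  "George", "Henry", "Arthur", "Edward", "Santiago", "Mateo", "Sebastián",
  "Nicolás", "Felipe", "Gustavo", "Raj", "Arjun", "Vikram", "Sanjay",
  "Wei", "Jun", "Hiroshi", "Kenji", "Takeshi", "Min-Jun", "Ji-Ho"
)

SURNAMES <- c(
  "Müller", "Schmidt", "Schneider", "Fischer", "Weber", "Meyer",
  "Wagner", "Becker", "Schulz", "Hoffmann", "Koch", "Bauer", "Richter",
  "Klein", "Wolf", "Neumann", "Schwarz", "Zimmermann", "Braun", "Krüger",
  "Rossi", "Russo", "Ferrari", "Esposito", "Bianchi", "Romano", "Colombo",
  "Ricci", "Marino", "Greco", "Bruno", "Gallo", "Conti", "DeLuca",
  "Mancini", "Costa", "Giordano", "Rizzo", "Lombardi", "Moretti",
  "Martin", "Bernard", "Dubois", "Durand", "Lefebvre", "Moreau", "Laurent",
  "Simon", "Michel", "Leroy", "Roux", "David", "Bertrand", "Morel",
  "Fournier", "Girard", "García", "Fernández", "González",
  "Rodríguez", "López", "Martínez", "Sánchez",
  "Pérez", "Gómez", "Martín", "Jiménez", "Ruiz",
  "Hernández", "Díaz", "Moreno", "Álvarez", "Romero",
  "Navarro", "Torres", "Silva", "Santos", "Ferreira", "Pereira", "Oliveira",
  "Costa", "Rodrigues", "Martins", "Sousa", "Fonseca", "Nowak", "Kowalski",
  "Wiśniewski", "Wójcik", "Kowalczyk", "Kamiński",
  "Lewandowski", "Zieliński", "Szymański", "Woźniak",
  "Novák", "Svoboda", "Novotný", "Dvořák",
  "Černý", "Procházka", "Horváth", "Kovács",
  "Tóth", "Szabó", "Nagy", "Varga", "Kiss", "Molnár",
  "Popović", "Jovanović", "Petrović", "Nikolić",
  "Marković", "Đorđević", "Stojanović", "Ivanov",
  "Petrov", "Smirnov", "Kuznetsov", "Popov", "Volkov", "Sokolov",
  "Smith", "Jones", "Taylor", "Brown", "Williams", "Wilson", "Johnson",
  "Davies", "Robinson", "Wright", "Thompson", "Evans", "Walker", "White",
  "Roberts", "Green", "Hall", "Wood", "Jackson", "Clarke", "Yilmaz",
  "Kaya", "Demir", "Çelik", "Şahin", "Yıldız",
  "Yıldırım", "Öztürk", "Aydın", "Özdemir",
  "Haddad", "Khoury", "Nasser", "Amari", "Mansour", "Okafor", "Okoro",
  "Eze", "Mensah", "Osei", "Diallo", "Traoré", "Koné", "Ndiaye",
  "Mokonzi", "Ilunga", "Kabila", "Tshisekedi", "Mbuyi", "Kalala",
  "Fernándes", "Morales", "Castro", "Vargas", "Ramírez", "Flores",
  "Acosta", "Medina", "Rojas", "Molina", "Ortiz", "Suárez", "Herrera",
  "Aguirre", "Giménez", "Singh", "Kumar", "Sharma", "Patel", "Gupta",
  "Mehta", "Reddy", "Rao", "Chen", "Wang", "Li", "Zhang", "Liu", "Yang",
  "Huang", "Zhao", "Tanaka", "Suzuki", "Takahashi", "Watanabe", "Sato",
  "Kim", "Lee", "Park", "Choi", "Nguyen", "Tran", "Pham", "Hoang"
)

# Syllables for the generated rare-surname tail.
SURNAME_SYL_A <- c("Bar", "Bel", "Cor", "Dal", "Fen", "Gal", "Hol", "Jas",
                   "Kel", "Lan", "Mar", "Nor", "Or", "Pel", "Quin", "Ras",
                   "Sal", "Tor", "Ul", "Ven", "Wil", "Zan", "Bren", "Cas",
                   "Dom", "Est", "Fal", "Gris", "Hern", "Iv")
SURNAME_SYL_B <- c("ba", "den", "der", "do", "ga", "gen", "ki", "la", "len",
                   "li", "lo", "ma", "men", "mi", "na", "nel", "ni", "no",
                   "ra", "ren", "ri", "ro", "sa", "sen", "si", "so", "ta",
                   "te", "ti", "to")
SURNAME_SYL_C <- c("cci", "dez", "dt", "ff", "k", "kis", "kov", "la", "ller",
                   "lli", "man", "mov", "ni", "nov", "ny", "res", "rra", "rri",
                   "s", "sen", "ski", "son", "sson", "stra", "tti", "tz",
                   "vic", "vich", "wski", "z")
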