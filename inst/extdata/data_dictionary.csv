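column,unit,description
specimen_id,-,specimen identifier
group,-,healthy or osteoporosis
level_index,-,1-based index of the sampling level (distal to proximal)
level_fraction,-,sampling position as a fraction of biomechanical length
total_area,mm^2,area enclosed by the periosteal contour (TA)
medullary_area,mm^2,area enclosed by the endosteal contour (MA)
cortical_area,mm^2,cortical bone area CA = TA - MA
periosteal_perimeter,mm,perimeter of the periosteal contour
endosteal_perimeter,mm,perimeter of the endosteal contour
thickness_min,mm,minimum radial cortical thickness over the semilandmark rays
thickness_mean,mm,mean radial cortical thickness over the semilandmark rays
thickness_max,mm,maximum radial cortical thickness over the semilandmark rays
centroid_x,mm,x (mediolateral) coordinate of the cortical-area centroid
centroid_y,mm,y (anteroposterior) coordinate of the cortical-area centroid
Ix,mm^4,second moment of area about the centroidal mediolateral axis
Iy,mm^4,second moment of area about the centroidal anteroposterior axis
Ixy,mm^4,product of inertia about the centroidal axes
Imin,mm^4,minimum principal second moment of area
Imax,mm^4,maximum principal second moment of area
theta,rad,principal-axis angle relative to the mediolateral axis; folded into (-pi/4. pi/4]
J,mm^4,polar moment of inertia J = Ix + Iy
dx,mm,maximum periosteal chord distance from the centroidal y axis
dy,mm,maximum periosteal chord distance from the centroidal x axis
dx_theta,mm,dx after rotating the section into the principal frame
dy_theta,mm,dy after rotating the section into the principal frame
rmax,mm,maximum radial distance from the centroid to the periosteal contour
Zx,mm^3,section modulus about the mediolateral axis (Ix / dy)
Zy,mm^3,section modulus about the anteroposterior axis (Iy / dx)
Zmin,mm^3,minimum section modulus (Imin / dx_theta)
Zmax,mm^3,maximum section modulus (Imax / dy_theta)
Zpol,mm^3,polar section modulus (J / rmax)
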